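Package: pataka
Title: Speech Rhythm and Articulation Screening for Parkinsonism from
    Syllable-Repetition Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a speech-based Parkinsonism screening protocol built
    on rhythmic repetition of the syllable sequence PA-TA-KA under four
    auditory feedback conditions. Extracts five rhythm and articulation
    parameters from trial audio (percentage of whispered trials, speech
    errors per second, reaction time, syllabic rate from the envelope
    modulation spectrum, and rhythmic structure consistency across trials),
    compares groups with Mann-Whitney tests, Benjamini-Hochberg false
    discovery rate control and rank-biserial effect sizes, and evaluates
    random-forest classifiers with repeated leave-one-out cross-validation.
    Includes synthetic stimulus, trial and cohort generators so the full
    pipeline can be exercised end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
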