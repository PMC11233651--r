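test_that("speech intervals recover a known speech span", {
  rec <- synthesize_trial(trial_synth_spec(onset_delay = 0.5,
                                           n_syllables = 18, seed = 2))
  iv <- detect_speech_intervals(rec$samples, rec$sample_rate)
  expect_s3_class(iv, "speech_intervals")
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$start[1] - 0.5), 0.025)
  expect_lt(abs(iv$end[1] - 5.0), 0.075)  # last burst decays into noise
})

test_that("degenerate inputs: silence, immediate speech, short input", {
  expect_equal(nrow(detect_speech_intervals(numeric(16000), 16000)), 0)
  expect_true(is.na(speech_onset(detect_speech_intervals(numeric(16000),
                                                         16000))))
  # speech with a sharp start at t = 0: first interval starts exactly there
  fs <- 16000
  x <- c(sin(2 * pi * 300 * seq_len(fs) / fs), numeric(fs))
  iv <- detect_speech_intervals(x, fs)
  expect_equal(iv$start[1], 0.0)
  expect_error(detect_speech_intervals(numeric(100), 16000), "0.2 s")
})

test_that("onsets are recovered within 25 ms and shift with prepended silence", {
  for (onset in c(0.2, 0.6, 1.0)) {
    rec <- synthesize_trial(trial_synth_spec(onset_delay = onset,
                                             n_syllables = 16,
                                             seed = round(1000 * onset)))
    got <- speech_onset(detect_speech_intervals(rec$samples,
                                                rec$sample_rate))
    expect_lt(abs(got - onset), 0.025)
  }
  # onset monotonicity under an s-second silent prefix
  rec <- synthesize_trial(trial_synth_spec(onset_delay = 0.3,
                                           n_syllables = 16, seed = 77))
  base <- speech_onset(detect_speech_intervals(rec$samples,
                                               rec$sample_rate))
  s <- 0.4
  shifted <- c(numeric(round(s * rec$sample_rate)), rec$samples)
  got <- speech_onset(detect_speech_intervals(shifted, rec$sample_rate))
  expect_lt(abs(got - (base + s)), 0.01)
})

test_that("interval detection matches the sample-level oracle on toys", {
  fs <- 8000
  set.seed(6)
  for (k in 1:5) {
    x <- numeric(0.5 * fs)
    a <- sample(200:1200, 1)
    b <- a + sample(800:2000, 1)
    x[a:b] <- sin(2 * pi * 300 * seq_len(b - a + 1) / fs)
    got <- detect_speech_intervals(x, fs)
    want <- oracle_intervals(x, fs)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start, tolerance = 1e-9)
    expect_equal(got$end, want$end, tolerance = 1e-9)
  }
})

test_that("voicing separates periodic from noise-source trials", {
  rec <- synthesize_trial(trial_synth_spec(voiced = TRUE, onset_delay = 0.3,
                                           seed = 51))
  vr <- voiced_duration(rec$samples, rec$sample_rate)
  expect_gte(vr$voiced_duration, 4.5)
  expect_lte(vr$voiced_duration, 5.5)

  wrec <- synthesize_trial(trial_synth_spec(voiced = FALSE,
                                            onset_delay = 0.3, seed = 52))
  wv <- voiced_duration(wrec$samples, wrec$sample_rate)
  expect_lt(wv$voiced_duration, 0.2)

  expect_equal(voiced_duration(numeric(16000), 16000)$voiced_duration, 0)
})

test_that("whisper decision is amplitude invariant", {
  rec <- synthesize_trial(trial_synth_spec(voiced = TRUE, seed = 53))
  v1 <- voiced_duration(rec$samples, rec$sample_rate)$voiced_duration
  v2 <- voiced_duration(0.05 * rec$samples, rec$sample_rate)$voiced_duration
  expect_equal(v1, v2)
  expect_identical(classify_whisper(v1), classify_whisper(v2))
})

test_that("whisper rule is a strict less-than at 10% of the phase", {
  expect_true(classify_whisper(0.0))
  expect_false(classify_whisper(0.55, threshold = 0.55))
  expect_true(classify_whisper(0.5499, threshold = 0.55))
  expect_false(classify_whisper(5.0))
  expect_error(classify_whisper(-1), "non-negative")
  expect_error(classify_whisper(1, threshold = 0), "> 0")
})
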