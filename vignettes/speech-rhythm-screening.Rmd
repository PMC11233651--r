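---
title: "Speech rhythm and articulation screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech rhythm and articulation screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pataka)
```

## The protocol

`pataka` implements the analysis side of a speech-based screening protocol
for Parkinsonism. Participants rhythmically repeat the syllable sequence
PA-TA-KA — a classic diadochokinetic (DDK) task probing articulatory motor
control — after listening to a rhythmic 3.75-s target (fifteen 250-ms
syllables, i.e. 4 syllables/s), then produce a 5.5-s repetition phase under
one of four auditory feedback conditions:

* **NF** — normal feedback: speak aloud, hear yourself;
* **RedF** — reduced: whisper, hear your whisper;
* **MF** — masked: whisper while white noise masks your feedback;
* **RepF** — replaced: whisper while an external voice speaks at the
  target rate.

Seven trials per condition are recorded. From each participant and
condition, five parameters are extracted:

1. **%whis** — percentage of whispered trials (whispering is required in
   RedF/MF/RepF; failure to whisper under altered feedback is the signal);
2. **Sp.Err** — manually annotated syllable errors per second of speech;
3. **RT** — mean speech-onset latency across trials;
4. **Rate** — mean syllabic rate;
5. **Rhy.Str.Cons** — rhythmic structure consistency across trials.

Groups (PD vs control) are compared with Mann–Whitney tests under
Benjamini–Hochberg FDR control with rank-biserial effect sizes, and the
discriminative value of the parameter set is assessed with a random forest
evaluated by repeated leave-one-out (LOO) cross-validation.

## Trial-level signal processing

**Envelope.** The speech envelope is the magnitude of the analytic signal
(absolute Hilbert transform), computed by the standard FFT construction.
Because the task is a train of non-coarticulated syllables, each envelope
cycle corresponds to one syllable.

**Envelope spectrum and syllabic rate.** The envelope is decimated in
anti-aliased stages to ~100 Hz, low-passed at 10 Hz with a zero-phase
4th-order Butterworth filter, mean-removed and zero-padded to a bin width
of ≤ 0.05 Hz before the FFT. The syllabic rate `fMAX` is the argmax of the
power spectrum inside the analysis band, 1–10 Hz by default (human
syllabic rates sit comfortably inside it); ties break toward the lower
frequency. Mean removal matters: without it the DC bin always wins the
argmax. The low-pass/decimate step removes carrier and f0 leakage;
`smooth = FALSE` recovers the raw magnitude-of-analytic-signal spectrum.
Whether correlations should use power or amplitude, band-limited or full
spectra, is not uniquely determined by the protocol; the package uses
band-limited power and exposes the band and smoothing as options.

**Rhythmic structure consistency.** The mean of the pairwise Pearson
correlations between the trials' envelope power spectra (the lower
triangle of the spectral correlation matrix). It is 1.0 for identical
trials, decreases with trial-to-trial timing jitter, is permutation
invariant in trial order, and is invariant to amplitude scaling. Spectra
must share one frequency grid; a zero-variance spectrum (a degenerate,
essentially silent trial) is a classed error rather than a silent `NA`.

**Speech onset.** A Praat-style silence annotator: 25-ms RMS frames every
5 ms; frames more than 25 dB below the trial's maximum frame intensity are
silent; silent runs shorter than 0.1 s are bridged; sounding runs shorter
than 0.05 s are dropped. The onset is the start of the first speech
interval. The annotator's parameter values are conventions of this
package, exposed in `silence_params()`, not protocol constants. The 5-ms
hop gives the ±25 ms onset accuracy the synthetic benchmarks check.

**Voicing and the whisper rule.** The protocol's whisper judgment was made
by ear; the package automates it with an equivalent acoustic criterion:
40-ms frames every 10 ms count as voiced when their normalized
autocorrelation has a peak ≥ 0.45 at a lag corresponding to 75–400 Hz and
the frame is above a −35 dB silence floor. A trial is whispered when
voiced speech totals strictly less than 0.55 s — 10% of the 5.5-s
repetition phase; the boundary value 0.55 s itself is *not* whispered.
Periodicity, not level, drives the decision, so it is invariant to
recording gain.

## Aggregation choices

* `errors_per_sec` divides the summed error annotations by
  (number of trials with detected speech) × 5.5 s, so silent trials do not
  dilute the rate; the protocol's definition leaves the denominator open.
* Rate, RT and consistency are computed over all trials with detected
  speech regardless of whisper status; restricting comparisons to
  conditions where groups match in spoken-aloud counts is the job of the
  comparison plan, not of feature extraction.
* Participants with a missing feature are median-imputed inside each LOO
  training fold (the fold's medians are applied to both the fold and the
  held-out row), because LOO cannot silently drop test subjects.

## Statistics

`mann_whitney_u()` wraps the standard two-sample Wilcoxon machinery: exact
two-sided p for combined n ≤ 20 without ties, normal approximation with
continuity and tie corrections otherwise; when all values are identical it
returns U = n₁n₂/2, p = 1. The rank-biserial correlation is the proportion
of favorable minus unfavorable cross-group pairs (ties count for neither):
r = 0.38 means favorable evidence outweighs unfavorable 69% to 31%. The
sign convention is fixed so that positive r means controls score higher —
this yields positive r for whispering ability and consistency and negative
r for errors and reaction time when the PD group is impaired.

The default comparison family is all 11 planned tests jointly — %whis in
RedF/MF/RepF plus the other four parameters in NF and RedF — corrected
together by Benjamini–Hochberg; the choice of family is a design decision
of this package (the protocol does not state one), and per-parameter
families can be requested by passing a narrower plan. Both raw and
adjusted p values are reported. Two-sided tests throughout.

## The classifier

Four feature sets are evaluated: Model 1 uses the five group-separating
parameters (%whis RepF, %whis MF, Sp.Err RedF, RT RedF, Rhy.Str.Cons NF);
Model 2 removes %whis MF; Model 3 removes %whis RepF; Model 4 is Model 2
plus age. The forest uses 500 trees and √p candidate features per split —
ordinary defaults, exposed in `model_spec()`, since the protocol does not
state hyperparameters. Each repeat runs full LOO (every participant held
out once), computes accuracy, sensitivity and specificity from the pooled
held-out predictions with PD as the positive class, and repeats are
averaged; repeats differ only through the forest's internal randomness.
All of it is deterministic under a master seed.

## What the synthetic data emulates — and what it does not

The generators exist so every stage is testable without clinical
recordings, at two levels.

**Waveforms.** A trial is a train of syllable bursts — a Hann amplitude
envelope over each 250-ms syllable slot — on either a harmonic source
(f0 = 200 Hz, ten 1/h-weighted harmonics; the pitch of the synthesized
protocol voice) or a 400–4000 Hz noise source for whisper, over white
background noise at a configurable SNR (default 30 dB; the rhythm and
onset benchmarks also run at 20 dB). The syllable's internal
consonant-gap/vowel structure is collapsed into a single burst: the
extracted metrics live on the envelope, which a single burst preserves.
Ground truth (onset, rate, per-syllable onsets, voicedness) is returned
with each trial. Default sample rate is 16 kHz — enough for voicing
detection up to 400 Hz with headroom, and cheap. These signals exercise
voicing detection, silence annotation and envelope rhythm; they make no
attempt at formant structure, realistic /pa/ /ta/ /ka/ articulation or
perceptual realism, so passing tests demonstrate correctness of the
measurement chain, not robustness to real-world acoustics (room noise,
breath sounds, coarticulation).

**Feature tables.** `emulate_cohort()` draws participant-level features
from *censored* normal distributions at the configured group means/SDs
(defaults: the 11 analysed parameter/condition cells for 28 PD and 30
control participants). Censoring — setting out-of-range draws to the
bound — rather than renormalized truncation is deliberate: it keeps every
cell's sample mean at the configured mean (renormalized truncation shifts
heavily-truncated cells, e.g. an error rate with mean 0.022 and SD 0.076
censored at zero, by several standard errors) and reproduces the pile-up
at 0% and 100% that percent-of-seven-trials features show in real cohorts.
Features are drawn independently across parameters; real parameters are
correlated (a configurable correlation structure would be an extension),
so emulated cohorts are a tool for power/type-I behavior of the testing
machinery, not a substitute for participant data. Classifier accuracy on
emulated cohorts is accordingly lower than what correlated real features
support.

## Numerical and degenerate-input behavior

* Spectra computed from equal-duration trials at one sample rate share
  their frequency grid by construction (fixed decimation target, fixed
  zero-padded FFT length); `rhythm_consistency()` refuses mismatched
  grids.
* A flat spectrum (silence) raises a classed "no rhythmic peak" error;
  `measure_trial()` converts it to a missing rate for that trial.
* All-silent trials yield zero speech intervals (not an error), a missing
  onset, and count as whispered; they stay in the %whis denominator and
  leave the RT/rate/consistency denominators.
* Determinism: every stochastic routine takes a seed; identical seeds give
  bit-identical waveforms, tables and reports. Child seeds are derived
  below 2³¹.

## Problem sizes used in the checks

The packaged test-suite benchmarks run at deliberately small scales: 7
trials × 20 replicate seeds for the jitter-monotonicity check, 400
emulated cohorts for the power check (the weakest pair's per-seed power is
≈ 0.57, so a few hundred replicates are needed to measure a majority
reliably), 100 null cohorts for type-I behavior, and 1–3 LOO repeats with
reduced forests for the classifier sanity checks. Full-scale runs (100
repeats, 500 trees) go through the same code paths via `run_pipeline()`.

## Known limitations

* Error counting is annotation-driven: the protocol counts syllable
  repetitions/exchanges/misarticulations manually, and the package takes
  them from the trial manifest. No syllable-identity recognition.
* The whisper detector is an acoustic proxy for an expert's auditory
  judgment; its harmonicity threshold (0.45) is a convention validated on
  synthetic voiced/whispered material only.
* The cohort emulator matches first and second moments per cell, not the
  joint distribution; between-parameter correlations and participant-level
  idiosyncrasies are absent.
* One count discrepancy in the source cohort description (28 vs 30 PD
  participants) is resolved in favor of the methods-level figure: defaults
  use 28 PD / 30 controls.
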