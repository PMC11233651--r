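#' Specification of one synthetic syllable-repetition trial
#'
#' Describes a trial of the repetition phase of the protocol: a train of
#' syllable bursts (voiced or whispered) starting after an onset delay,
#' embedded in background noise at a given signal-to-noise ratio.
#'
#' @param syllable_duration Duration of one syllable in seconds.
#' @param n_syllables Number of syllables in the train.
#' @param syllabic_rate Syllable production rate in Hz (syllables per second).
#' @param onset_delay Silence before the first syllable, seconds.
#' @param rate_jitter_sd Standard deviation (seconds) of Gaussian timing
#'   perturbation applied to each syllable onset.
#' @param voiced If `TRUE`, syllables use a periodic glottal-like source at
#'   `f0`; if `FALSE`, a band-limited noise (whisper) source.
#' @param f0 Fundamental frequency of the voiced source, Hz.
#' @param snr_db Speech-to-background-noise ratio in dB.
#' @param phase_duration Total duration of the repetition phase, seconds.
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param seed Integer seed; fixes jitter, source noise and background noise.
#' @return An object of class `trial_synth_spec`.
#' @export
trial_synth_spec <- function(syllable_duration = 0.25,
                             n_syllables = 20,
                             syllabic_rate = 4,
                             onset_delay = 0.5,
                             rate_jitter_sd = 0,
                             voiced = TRUE,
                             f0 = 200,
                             snr_db = 30,
                             phase_duration = 5.5,
                             sample_rate = 16000,
                             seed = NULL) {
  if (!is_scalar_number(syllable_duration) || syllable_duration <= 0)
    stop_pataka("syllable_duration must be > 0", "pataka_spec_error")
  if (!is_scalar_number(syllabic_rate) || syllabic_rate <= 0)
    stop_pataka("syllabic_rate must be > 0", "pataka_spec_error")
  if (!is_scalar_number(rate_jitter_sd) || rate_jitter_sd < 0)
    stop_pataka("rate_jitter_sd must be >= 0", "pataka_spec_error")
  if (!is_scalar_number(onset_delay) || onset_delay < 0)
    stop_pataka("onset_delay must be >= 0", "pataka_spec_error")
  if (sample_rate < 8000)
    stop_pataka("sample_rate must be >= 8000 Hz", "pataka_spec_error")
  if (n_syllables / syllabic_rate + onset_delay > phase_duration + 1e-9)
    stop_pataka(
      "n_syllables / syllabic_rate + onset_delay exceeds phase_duration",
      "pataka_spec_error")
  structure(list(
    syllable_duration = syllable_duration, n_syllables = as.integer(n_syllables),
    syllabic_rate = syllabic_rate, onset_delay = onset_delay,
    rate_jitter_sd = rate_jitter_sd, voiced = isTRUE(voiced), f0 = f0,
    snr_db = snr_db, phase_duration = phase_duration,
    sample_rate = as.integer(sample_rate), seed = seed),
    class = "trial_synth_spec")
}

# One syllable burst: a Hann amplitude envelope over the syllable slot
# applied to a periodic (voiced) or band-limited noise (whisper) carrier.
syllable_burst <- function(n, sample_rate, voiced, f0, amplitude = 1,
                           phase = 0) {
  t <- seq_len(n) / sample_rate
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  if (voiced) {
    h <- 1:10
    carrier <- colSums(sin(outer(h * 2 * pi * f0, t) + phase * h) / h)
    carrier <- carrier / max(abs(carrier))
  } else {
    noise <- stats::rnorm(n + 200)
    bp <- signal::butter(4, c(400, 4000) / (sample_rate / 2), type = "pass")
    carrier <- signal::filtfilt(bp, noise)[101:(n + 100)]
    carrier <- carrier / max(abs(carrier))
  }
  amplitude * win * carrier
}

#' Synthesize one repetition-phase trial with known ground truth
#'
#' @param spec A [trial_synth_spec()].
#' @return An object of class `trial_recording`: list with `samples`,
#'   `sample_rate` and `ground_truth` (`onset`, `rate`, `voiced_duration`,
#'   `voiced`, `syllable_onsets`).
#' @export
synthesize_trial <- function(spec) {
  if (!inherits(spec, "trial_synth_spec"))
    spec <- do.call(trial_synth_spec, as.list(spec))
  fs <- spec$sample_rate
  with_seed(spec$seed, {
    n_total <- round(spec$phase_duration * fs)
    x <- numeric(n_total)
    period <- 1 / spec$syllabic_rate
    onsets <- spec$onset_delay + (seq_len(spec$n_syllables) - 1) * period
    if (spec$rate_jitter_sd > 0)
      onsets <- onsets + stats::rnorm(spec$n_syllables, 0, spec$rate_jitter_sd)
    onsets <- pmax(onsets, 0)
    n_burst <- round(spec$syllable_duration * fs)
    for (k in seq_len(spec$n_syllables)) {
      i0 <- round(onsets[k] * fs) + 1L
      i1 <- min(i0 + n_burst - 1L, n_total)
      if (i0 > n_total) next
      burst <- syllable_burst(n_burst, fs, spec$voiced, spec$f0)
      x[i0:i1] <- x[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
    }
    speech_rms <- sqrt(mean(x[x != 0]^2))
    if (is.finite(spec$snr_db) && speech_rms > 0) {
      noise_rms <- speech_rms / 10^(spec$snr_db / 20)
      x <- x + stats::rnorm(n_total, 0, noise_rms)
    }
    x <- x / max(abs(x))
    structure(list(
      samples = x, sample_rate = fs,
      ground_truth = list(
        onset = onsets[1],
        rate = spec$syllabic_rate,
        voiced = spec$voiced,
        voiced_duration = if (spec$voiced)
          spec$n_syllables * spec$syllable_duration else 0,
        syllable_onsets = onsets)),
      class = "trial_recording")
  })
}

#' Synthesize the rhythmic PA-TA-KA target stimulus
#'
#' Builds the 3.75-s target audio used in the listening phase: fifteen
#' 250-ms syllables (a three-syllable pattern repeated five times) at
#' 4 syllables/s, spoken (voiced at `f0`) or whispered.
#'
#' @param voiced If `TRUE`, the spoken target; if `FALSE`, the whispered one.
#' @param sample_rate Sampling rate in Hz.
#' @param f0 Fundamental frequency of the voiced target, Hz.
#' @param syllable_duration Seconds per syllable (default 0.25 s).
#' @param n_repeats Number of repetitions of the three-syllable pattern.
#' @param seed Integer seed (whisper source noise).
#' @return A `trial_recording` of duration
#'   `3 * n_repeats * syllable_duration` seconds.
#' @export
synthesize_target_audio <- function(voiced = TRUE, sample_rate = 16000,
                                    f0 = 200, syllable_duration = 0.25,
                                    n_repeats = 5, seed = 1L) {
  fs <- sample_rate
  n_syll <- 3L * as.integer(n_repeats)
  n_burst <- round(syllable_duration * fs)
  # the three syllables differ in amplitude and source phase so the pattern
  # repeats at the sequence level while the envelope pulses at 4/s
  amp <- c(1, 0.85, 0.7)
  phs <- c(0, pi / 3, 2 * pi / 3)
  with_seed(seed, {
    x <- unlist(lapply(seq_len(n_syll), function(k) {
      j <- (k - 1L) %% 3L + 1L
      syllable_burst(n_burst, fs, voiced, f0, amplitude = amp[j],
                     phase = phs[j])
    }))
    x <- x / max(abs(x))
    structure(list(
      samples = x, sample_rate = fs,
      ground_truth = list(onset = 0, rate = 1 / syllable_duration,
                          voiced = voiced,
                          voiced_duration = if (voiced)
                            n_syll * syllable_duration else 0,
                          syllable_onsets = (seq_len(n_syll) - 1) *
                            syllable_duration)),
      class = "trial_recording")
  })
}

#' Synthesize a masker signal for the altered-feedback conditions
#'
#' @param kind `"noise"` (white noise, as in the Masked condition) or
#'   `"exogenous_speech"` (a rhythmic train of random voiced syllables at
#'   4 syllables/s, as in the Replaced condition).
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param syllable_duration Seconds per syllable for `exogenous_speech`.
#' @param f0 Pitch of the exogenous voice, Hz.
#' @return Numeric waveform of `round(duration * sample_rate)` samples.
#' @export
synthesize_masker <- function(kind = c("noise", "exogenous_speech"),
                              duration = 5.5, sample_rate = 16000,
                              seed = NULL, syllable_duration = 0.25,
                              f0 = 200) {
  kind <- match.arg(kind)
  if (!is_scalar_number(duration) || duration <= 0)
    stop_pataka("duration must be > 0", "pataka_spec_error")
  fs <- sample_rate
  n_total <- round(duration * fs)
  with_seed(seed, {
    if (kind == "noise") {
      x <- stats::rnorm(n_total)
    } else {
      n_syll <- floor(duration / syllable_duration)
      n_burst <- round(syllable_duration * fs)
      # random syllable identities emulated by random amplitude/phase draws
      x <- unlist(lapply(seq_len(n_syll), function(k) {
        syllable_burst(n_burst, fs, voiced = TRUE, f0 = f0,
                       amplitude = stats::runif(1, 0.7, 1),
                       phase = stats::runif(1, 0, 2 * pi))
      }))
      x <- c(x, numeric(n_total - length(x)))
    }
    x / max(abs(x))
  })
}
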