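#' Amplitude envelope via the analytic signal
#'
#' The envelope is the pointwise magnitude of the analytic signal, i.e. the
#' absolute value of the waveform's Hilbert transform, computed with the
#' standard frequency-domain construction (positive frequencies doubled,
#' negative frequencies zeroed).
#'
#' @param waveform Numeric waveform (non-empty, finite).
#' @param sample_rate Sampling rate in Hz.
#' @return Object of class `envelope`: list with `samples` (non-negative,
#'   same length as `waveform`) and `sample_rate`.
#' @export
compute_envelope <- function(waveform, sample_rate) {
  if (length(waveform) == 0 || !is.numeric(waveform))
    stop_pataka("waveform must be a non-empty numeric vector",
                "pataka_input_error")
  if (any(!is.finite(waveform)))
    stop_pataka("waveform contains non-finite values", "pataka_input_error")
  n <- length(waveform)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(stats::fft(waveform) * h, inverse = TRUE) / n
  structure(list(samples = Mod(analytic), sample_rate = sample_rate),
            class = "envelope")
}

#' Power spectrum of the speech envelope
#'
#' Computes the FFT power spectrum of the mean-removed envelope, restricted
#' to a modulation band. By default the envelope is first low-passed at
#' 10 Hz and decimated to ~100 Hz, which removes carrier/f0 leakage before
#' the modulation-rate analysis; set `smooth = FALSE` for the raw
#' magnitude-of-analytic-signal spectrum.
#'
#' @param env An [compute_envelope()] result.
#' @param band Length-2 numeric, analysis band in Hz (default 1-10 Hz,
#'   covering human syllabic rates).
#' @param smooth Low-pass (10 Hz, 4th-order Butterworth, zero-phase) and
#'   decimate to ~100 Hz before the FFT.
#' @param resolution Target frequency resolution in Hz; the envelope is
#'   zero-padded so that the bin width is at most this value.
#' @return Object of class `envelope_spectrum`: `freq` (Hz, ascending
#'   uniform grid), `power` (non-negative), `band`, `bin_width`.
#' @export
envelope_spectrum <- function(env, band = c(1, 10), smooth = TRUE,
                              resolution = 0.05) {
  stopifnot(inherits(env, "envelope"))
  fs <- env$sample_rate
  x <- env$samples
  dur <- length(x) / fs
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop_pataka("band must lie within [0, Nyquist] with low < high",
                "pataka_input_error")
  if (band[1] > 0 && band[1] < 1 / dur)
    stop_pataka("band low edge below the minimum resolvable frequency (1/duration)",
                "pataka_input_error")
  if (smooth && fs > 200) {
    # stagewise decimation to ~100 Hz (anti-aliased per stage), then a
    # zero-phase 10-Hz low-pass at the decimated rate, where the filter is
    # well-conditioned
    dec <- max(1L, floor(fs / 100))
    for (q in decimation_stages(dec))
      x <- signal::decimate(x, q)
    fs <- fs / dec
    lp <- signal::butter(4, min(10 / (fs / 2), 0.9), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(max(length(x), fs / resolution)))
  p <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq >= band[1] & freq <= band[2]
  structure(list(freq = freq[keep], power = p[keep], band = band,
                 bin_width = fs / nfft),
            class = "envelope_spectrum")
}

# Split an integer decimation factor into stages of at most 10.
decimation_stages <- function(dec) {
  stages <- integer(0)
  while (dec > 1L) {
    q <- 10L
    while (q > 1L && dec %% q != 0L) q <- q - 1L
    if (q == 1L) q <- dec  # prime factor > 10: decimate in one pass
    stages <- c(stages, q)
    dec <- dec %/% q
  }
  stages
}

#' Syllabic rate: frequency of maximal envelope-spectrum power
#'
#' The syllabic rate (often written fMAX) is the frequency with the largest
#' power in the envelope modulation spectrum; for trains of non-coarticulated
#' syllables each envelope cycle is one syllable, so this approximates
#' syllables per second. Ties break toward the lower frequency.
#'
#' @param spec An [envelope_spectrum()].
#' @param floor_power Numerical floor below which the spectrum is treated as
#'   flat (no rhythmic peak).
#' @return Peak frequency in Hz.
#' @export
syllabic_rate <- function(spec, floor_power = 1e-12) {
  stopifnot(inherits(spec, "envelope_spectrum"))
  if (length(spec$power) == 0)
    stop_pataka("empty spectrum", "pataka_input_error")
  m <- max(spec$power)
  if (!is.finite(m) || m <= floor_power * length(spec$power))
    stop_pataka("no rhythmic peak: envelope spectrum is flat",
                "pataka_no_peak")
  spec$freq[which.max(spec$power)]  # which.max returns the first (lowest) max
}

#' Rhythmic structure consistency across trials
#'
#' The mean of the pairwise Pearson correlations between the envelope power
#' spectra of a participant's trials within one condition (equivalently, the
#' mean of the lower-triangle elements of the trials' spectral correlation
#' matrix). Values near 1 indicate the same rhythmic structure reproduced
#' trial after trial.
#'
#' @param spectra List of >= 2 [envelope_spectrum()] objects on identical
#'   frequency grids.
#' @return Scalar in \[-1, 1\].
#' @export
rhythm_consistency <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 2)
    stop_pataka("need at least two spectra", "pataka_input_error")
  grids <- lapply(spectra, `[[`, "freq")
  for (g in grids[-1])
    if (!isTRUE(all.equal(g, grids[[1]], tolerance = 1e-9)))
      stop_pataka("spectra are not on identical frequency grids",
                  "pataka_input_error")
  pw <- vapply(spectra, `[[`, numeric(length(grids[[1]])), "power")
  if (any(apply(pw, 2, stats::sd) == 0))
    stop_pataka("degenerate trial: zero-variance spectrum",
                "pataka_degenerate_trial")
  cm <- stats::cor(pw)
  mean(cm[lower.tri(cm)])
}
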