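#' Silence-annotator parameters
#'
#' Praat-style defaults for the intensity-based silence annotation used to
#' find speech intervals and the speech onset. The threshold is relative to
#' the trial's maximum frame intensity.
#'
#' @param silence_threshold_db Frames more than this many dB below the trial
#'   maximum are silent (default -25 dB).
#' @param min_silent Minimum duration of a silent interval, seconds; shorter
#'   dips are bridged into the surrounding speech.
#' @param min_sounding Minimum duration of a sounding interval, seconds;
#'   shorter blips are discarded.
#' @param frame Analysis frame length, seconds.
#' @param hop Frame hop, seconds (sets onset resolution).
#' @return List of class `silence_params`.
#' @export
silence_params <- function(silence_threshold_db = -25, min_silent = 0.1,
                           min_sounding = 0.05, frame = 0.025, hop = 0.005) {
  stopifnot(silence_threshold_db < 0, min_silent > 0, min_sounding > 0,
            frame > 0, hop > 0, hop <= frame)
  structure(list(silence_threshold_db = silence_threshold_db,
                 min_silent = min_silent, min_sounding = min_sounding,
                 frame = frame, hop = hop),
            class = "silence_params")
}

# Frame a waveform into an L x n_frames matrix (zero-padded tail).
frame_matrix <- function(x, frame_len, hop_len) {
  starts <- seq(1L, max(1L, length(x) - frame_len + 1L), by = hop_len)
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  m <- matrix(0, nrow = frame_len, ncol = length(starts))
  ok <- idx <= length(x)
  m[ok] <- x[idx[ok]]
  list(frames = m, starts = starts)
}

# Merge a logical frame sequence into runs, bridging short silences and
# dropping short sounding runs, following the silence-annotator convention.
merge_frame_runs <- function(sounding, hop, min_silent, min_sounding) {
  r <- rle(sounding)
  # silent runs shorter than min_silent flanked by speech become speech
  if (length(r$lengths) > 2) {
    for (i in 2:(length(r$lengths) - 1))
      if (!r$values[i] && r$lengths[i] * hop < min_silent)
        r$values[i] <- TRUE
  }
  sounding <- inverse.rle(r)
  r <- rle(sounding)
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] * hop < min_sounding)
      r$values[i] <- FALSE
  inverse.rle(r)
}

#' Detect speech intervals by silence annotation
#'
#' Classifies each time frame as silence or speech from its RMS intensity
#' relative to the trial maximum, then merges frames into intervals:
#' sub-threshold runs shorter than `min_silent` are bridged, sounding runs
#' shorter than `min_sounding` are dropped.
#'
#' @param waveform Numeric waveform (>= 0.2 s).
#' @param sample_rate Sampling rate, Hz.
#' @param params A [silence_params()].
#' @return Object of class `speech_intervals`: data.frame with `start` and
#'   `end` (seconds), detection parameters in attribute `params`. An
#'   all-silent input yields zero rows.
#' @export
detect_speech_intervals <- function(waveform, sample_rate,
                                    params = silence_params()) {
  if (length(waveform) < 0.2 * sample_rate)
    stop_pataka("waveform shorter than 0.2 s", "pataka_input_error")
  frame_len <- round(params$frame * sample_rate)
  hop_len <- max(1L, round(params$hop * sample_rate))
  fm <- frame_matrix(waveform, frame_len, hop_len)
  rms <- sqrt(colMeans(fm$frames^2))
  db <- 20 * log10(rms + .Machine$double.xmin)
  sounding <- db > max(db) + params$silence_threshold_db &
    rms > .Machine$double.eps
  sounding <- merge_frame_runs(sounding, params$hop, params$min_silent,
                               params$min_sounding)
  r <- rle(sounding)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  iv <- data.frame(
    start = (fm$starts[starts_i[keep]] - 1L) / sample_rate,
    end = pmin((fm$starts[ends_i[keep]] - 1L + frame_len) / sample_rate,
               length(waveform) / sample_rate))
  structure(iv, params = params, class = c("speech_intervals", "data.frame"))
}

#' Speech onset time
#'
#' The start of the first detected speech interval (the first speech point
#' preceded by silence, or 0 when speech starts immediately). `NA` when no
#' speech was detected.
#'
#' @param intervals A [detect_speech_intervals()] result.
#' @return Onset in seconds, or `NA_real_`.
#' @export
speech_onset <- function(intervals) {
  stopifnot(inherits(intervals, "speech_intervals"))
  if (nrow(intervals) == 0) return(NA_real_)
  intervals$start[1]
}

#' Voicing-detector parameters
#'
#' @param f0_min,f0_max Fundamental-frequency search range, Hz.
#' @param frame Frame length, seconds.
#' @param hop Frame hop, seconds.
#' @param harmonicity_threshold Minimum normalized autocorrelation peak for
#'   a frame to count as voiced.
#' @param silence_floor_db Frames more than this many dB below the maximum
#'   frame level are unvoiced regardless of periodicity.
#' @return List of class `voicing_params`.
#' @export
voicing_params <- function(f0_min = 75, f0_max = 400, frame = 0.04,
                           hop = 0.01, harmonicity_threshold = 0.45,
                           silence_floor_db = -35) {
  stopifnot(f0_min > 0, f0_max > f0_min, frame > 0, hop > 0,
            harmonicity_threshold > 0, harmonicity_threshold < 1)
  structure(list(f0_min = f0_min, f0_max = f0_max, frame = frame, hop = hop,
                 harmonicity_threshold = harmonicity_threshold,
                 silence_floor_db = silence_floor_db),
            class = "voicing_params")
}

#' Voiced-speech duration via short-time autocorrelation
#'
#' Frames are voiced when their normalized autocorrelation has a peak of at
#' least `harmonicity_threshold` at a lag inside the f0 search range
#' (i.e. the frame is periodic, indicating vocal-fold activation), and their
#' level is above the silence floor. Voiced duration is hop times the number
#' of voiced frames.
#'
#' @param waveform Numeric waveform (>= 0.2 s).
#' @param sample_rate Sampling rate, Hz (must resolve `f0_max`).
#' @param params A [voicing_params()].
#' @return Object of class `voicing_result`: `voiced_duration` (seconds),
#'   `frames` (data.frame of `time`, `is_voiced`), `params`.
#' @export
voiced_duration <- function(waveform, sample_rate,
                            params = voicing_params()) {
  if (length(waveform) < 0.2 * sample_rate)
    stop_pataka("waveform shorter than 0.2 s", "pataka_input_error")
  if (sample_rate < 2 * params$f0_max)
    stop_pataka("sample_rate too low for the f0 search range",
                "pataka_input_error")
  frame_len <- round(params$frame * sample_rate)
  hop_len <- max(1L, round(params$hop * sample_rate))
  fm <- frame_matrix(waveform, frame_len, hop_len)
  frames <- sweep(fm$frames, 2, colMeans(fm$frames))
  rms <- sqrt(colMeans(frames^2))
  db <- 20 * log10(rms + .Machine$double.xmin)
  audible <- db > max(db) + params$silence_floor_db
  # normalized autocorrelation of every frame at once via FFT
  nfft <- 2^ceiling(log2(2 * frame_len))
  padded <- rbind(frames, matrix(0, nfft - frame_len, ncol(frames)))
  ac <- Re(stats::mvfft(Mod(stats::mvfft(padded))^2, inverse = TRUE)) / nfft
  lag_lo <- max(2L, floor(sample_rate / params$f0_max))
  lag_hi <- min(frame_len - 1L, ceiling(sample_rate / params$f0_min))
  peak <- apply(ac[(lag_lo + 1L):(lag_hi + 1L), , drop = FALSE], 2, max)
  harmonicity <- ifelse(ac[1, ] > 0, peak / ac[1, ], 0)
  is_voiced <- audible & harmonicity >= params$harmonicity_threshold
  structure(list(
    voiced_duration = params$hop * sum(is_voiced),
    frames = data.frame(
      time = (fm$starts - 1L) / sample_rate + params$frame / 2,
      is_voiced = is_voiced,
      harmonicity = harmonicity),
    params = params),
    class = "voicing_result")
}

#' Whisper classification rule
#'
#' A trial counts as whispered when voiced speech (speech with vocal-fold
#' activation) occupies strictly less than `threshold` seconds — by default
#' 0.55 s, i.e. 10\% of the 5.5-s repetition phase.
#'
#' @param voiced_dur Voiced duration in seconds (>= 0), e.g. the
#'   `voiced_duration` element of a [voiced_duration()] result.
#' @param threshold Decision threshold in seconds (> 0).
#' @return `TRUE` if whispered.
#' @export
classify_whisper <- function(voiced_dur, threshold = 0.55) {
  if (inherits(voiced_dur, "voicing_result"))
    voiced_dur <- voiced_dur$voiced_duration
  if (!is_scalar_number(voiced_dur) || voiced_dur < 0)
    stop_pataka("voiced_dur must be a non-negative number",
                "pataka_input_error")
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop_pataka("threshold must be > 0", "pataka_input_error")
  voiced_dur < threshold
}

#' Export detected speech intervals for audit
#'
#' `write_intervals_csv` writes a BED-like `start,end,label` CSV;
#' `write_textgrid` writes a minimal Praat TextGrid with one interval tier
#' alternating silence/speech labels.
#'
#' @param intervals A [detect_speech_intervals()] result.
#' @param path Output file.
#' @param total_duration Total duration in seconds (TextGrid xmax);
#'   defaults to the last interval end.
#' @return `path`, invisibly.
#' @export
write_intervals_csv <- function(intervals, path) {
  stopifnot(inherits(intervals, "speech_intervals"))
  df <- as.data.frame(intervals)
  df$label <- "speech"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
write_textgrid <- function(intervals, path,
                           total_duration = max(0, intervals$end)) {
  stopifnot(inherits(intervals, "speech_intervals"))
  bounds <- sort(unique(c(0, intervals$start, intervals$end,
                          total_duration)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  labs <- vapply(starts, function(s)
    if (any(intervals$start <= s + 1e-12 & intervals$end > s + 1e-12))
      "sounding" else "silent", character(1))
  lines <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", sprintf("xmax = %.6f", total_duration),
    "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
    '        class = "IntervalTier"', '        name = "silences"',
    "        xmin = 0", sprintf("        xmax = %.6f", total_duration),
    sprintf("        intervals: size = %d", length(starts)),
    unlist(lapply(seq_along(starts), function(i) c(
      sprintf("        intervals [%d]:", i),
      sprintf("            xmin = %.6f", starts[i]),
      sprintf("            xmax = %.6f", ends[i]),
      sprintf('            text = "%s"', labs[i])))))
  writeLines(lines, path)
  invisible(path)
}
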