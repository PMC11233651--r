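#' Feature-extraction configuration
#'
#' Bundles every tunable constant of the trial-level feature extraction.
#' Defaults mirror the screening protocol: a 5.5-s repetition phase, a
#' whisper threshold of 10\% of that phase, and a 1-10 Hz modulation band
#' for the rhythm analysis.
#'
#' @param phase_duration Repetition-phase duration, seconds.
#' @param band Modulation-spectrum analysis band, Hz.
#' @param whisper_threshold Voiced-duration threshold of the whisper rule,
#'   seconds; defaults to `0.10 * phase_duration`.
#' @param silence A [silence_params()].
#' @param voicing A [voicing_params()].
#' @param smooth_envelope Low-pass/decimate the envelope before its FFT.
#' @return List of class `extraction_config`.
#' @export
extraction_config <- function(phase_duration = 5.5, band = c(1, 10),
                              whisper_threshold = 0.10 * phase_duration,
                              silence = silence_params(),
                              voicing = voicing_params(),
                              smooth_envelope = TRUE) {
  stopifnot(phase_duration > 0, length(band) == 2, whisper_threshold > 0)
  structure(list(phase_duration = phase_duration, band = band,
                 whisper_threshold = whisper_threshold, silence = silence,
                 voicing = voicing, smooth_envelope = smooth_envelope),
            class = "extraction_config")
}

#' Measure one trial: whisper flag, onset, envelope spectrum, syllabic rate
#'
#' Runs the full per-trial pipeline: silence annotation for the speech
#' onset, autocorrelation voicing for the whisper rule, and the envelope
#' modulation spectrum for the syllabic rate.
#'
#' @param recording A `trial_recording` (or list with `samples` and
#'   `sample_rate`), cropped to the repetition phase.
#' @param error_count Manually annotated syllable-error count for the trial.
#' @param config An [extraction_config()].
#' @return Object of class `trial_measurements`: `whis`, `voiced_duration`,
#'   `onset` (`NA` when no speech), `spectrum` (`NULL` when no speech),
#'   `f_max` (`NA` when no rhythmic peak), `speech_detected`, `error_count`.
#' @export
measure_trial <- function(recording, error_count = 0L,
                          config = extraction_config()) {
  x <- recording$samples
  fs <- recording$sample_rate
  stopifnot(is.numeric(x), is_scalar_number(fs))
  if (error_count < 0) stop_pataka("error_count must be >= 0",
                                   "pataka_input_error")
  iv <- detect_speech_intervals(x, fs, config$silence)
  onset <- speech_onset(iv)
  vr <- voiced_duration(x, fs, config$voicing)
  whis <- classify_whisper(vr$voiced_duration, config$whisper_threshold)
  speech_detected <- nrow(iv) > 0
  spectrum <- NULL
  f_max <- NA_real_
  if (speech_detected) {
    env <- compute_envelope(x, fs)
    spectrum <- envelope_spectrum(env, band = config$band,
                                  smooth = config$smooth_envelope)
    f_max <- tryCatch(syllabic_rate(spectrum),
                      pataka_no_peak = function(e) NA_real_)
  }
  structure(list(whis = whis, voiced_duration = vr$voiced_duration,
                 onset = onset, spectrum = spectrum, f_max = f_max,
                 speech_detected = speech_detected,
                 error_count = as.integer(error_count)),
            class = "trial_measurements")
}

#' Condition-level features from a participant's trials
#'
#' Aggregates the measurements of one participant's trials within one
#' feedback condition into the five screening parameters: percentage of
#' whispered trials, speech errors per second, mean reaction time, mean
#' syllabic rate, and rhythmic structure consistency across trials.
#'
#' @param measurements List of [measure_trial()] results (>= 1).
#' @param phase_duration Repetition-phase duration, seconds (errors-per-
#'   second denominator: trials with detected speech x this duration).
#' @return Object of class `condition_features`: `pct_whispered`,
#'   `errors_per_sec`, `mean_rt`, `mean_rate`, `rhythm_consistency` and
#'   `n_trials_used` (per-field counts). Fields are `NA` when no trial
#'   provides them; `pct_whispered` is always defined.
#' @export
condition_features <- function(measurements, phase_duration = 5.5) {
  if (length(measurements) < 1)
    stop_pataka("need at least one trial measurement", "pataka_input_error")
  stopifnot(all(vapply(measurements, inherits, logical(1),
                       "trial_measurements")))
  n <- length(measurements)
  whis <- vapply(measurements, `[[`, logical(1), "whis")
  onsets <- vapply(measurements, `[[`, numeric(1), "onset")
  rates <- vapply(measurements, `[[`, numeric(1), "f_max")
  errs <- vapply(measurements, `[[`, integer(1), "error_count")
  has_speech <- vapply(measurements, `[[`, logical(1), "speech_detected")
  spectra <- Filter(Negate(is.null),
                    lapply(measurements[has_speech & !is.na(rates)], `[[`,
                           "spectrum"))
  cons <- if (length(spectra) >= 2)
    rhythm_consistency(spectra) else NA_real_
  structure(list(
    pct_whispered = 100 * sum(whis) / n,
    errors_per_sec = if (any(has_speech))
      sum(errs[has_speech]) / (sum(has_speech) * phase_duration)
      else NA_real_,
    mean_rt = if (any(!is.na(onsets))) mean(onsets, na.rm = TRUE)
      else NA_real_,
    mean_rate = if (any(!is.na(rates))) mean(rates, na.rm = TRUE)
      else NA_real_,
    rhythm_consistency = cons,
    n_trials_used = list(whis = n, errors = sum(has_speech),
                         rt = sum(!is.na(onsets)),
                         rate = sum(!is.na(rates)),
                         consistency = length(spectra))),
    class = "condition_features")
}

#' The feedback conditions of the protocol
#'
#' `NF` normal feedback (speak aloud, hear self), `RedF` reduced (whisper,
#' hear self), `MF` masked (whisper, hear white noise), `RepF` replaced
#' (whisper, hear an external rhythmic voice).
#' @export
CONDITIONS <- c("NF", "RedF", "MF", "RepF")

# Short feature names used in cohort-table columns, per condition.
FEATURES <- c("whis", "SpErr", "RT", "Rate", "RhyStrCons")

feature_column <- function(feature, condition) paste0(feature, "_", condition)

#' Assemble the participant-level cohort feature table
#'
#' @param manifest Data.frame with one row per trial: `participant_id`,
#'   `group` (`"PD"` or `"control"`), `condition` (one of NF, RedF, MF,
#'   RepF), `trial_index`, optionally
#'   `age`. Duplicate (participant, condition, trial) keys are an error.
#' @param measurements List of [measure_trial()] results parallel to the
#'   manifest rows.
#' @param phase_duration Repetition-phase duration, seconds.
#' @return Object of class `cohort_table` (a data.frame): one row per
#'   participant with `participant_id`, `group`, `age` and a
#'   `<feature>_<condition>` column for each of the five features in each
#'   condition present in the manifest. Conditions without trials for a
#'   participant yield `NA` blocks.
#' @export
build_cohort_table <- function(manifest, measurements,
                               phase_duration = 5.5) {
  need <- c("participant_id", "group", "condition", "trial_index")
  if (!all(need %in% names(manifest)))
    stop_pataka(paste("manifest must have columns:",
                      paste(need, collapse = ", ")), "pataka_input_error")
  if (nrow(manifest) != length(measurements))
    stop_pataka("one measurement per manifest row required",
                "pataka_input_error")
  key <- paste(manifest$participant_id, manifest$condition,
               manifest$trial_index, sep = "/")
  if (anyDuplicated(key))
    stop_pataka(sprintf("duplicate trial key: %s", key[duplicated(key)][1]),
                "pataka_input_error")
  ids <- unique(manifest$participant_id)
  conds <- intersect(CONDITIONS, unique(manifest$condition))
  rows <- lapply(ids, function(id) {
    sel <- manifest$participant_id == id
    row <- list(participant_id = id,
                group = manifest$group[sel][1],
                age = if ("age" %in% names(manifest))
                  manifest$age[sel][1] else NA_real_)
    for (cond in conds) {
      csel <- sel & manifest$condition == cond
      if (!any(csel)) {
        vals <- rep(NA_real_, 5)
      } else {
        cf <- condition_features(measurements[which(csel)], phase_duration)
        vals <- c(cf$pct_whispered, cf$errors_per_sec, cf$mean_rt,
                  cf$mean_rate, cf$rhythm_consistency)
      }
      row[feature_column(FEATURES, cond)] <- as.list(vals)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = c("PD", "control"))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort feature table as CSV
#'
#' Numeric fields round-trip at full double precision (15 significant
#' digits).
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly. `read_cohort_csv`: a
#'   `cohort_table`.
#' @export
write_cohort_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("PD", "control"))
  class(df) <- c("cohort_table", "data.frame")
  df
}
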