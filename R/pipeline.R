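#' End-to-end run configuration
#'
#' Single configuration object for a full screening-analysis run. All
#' protocol constants are named here and nowhere hard-coded: 0.25-s
#' syllables, a 3.75-s listening target, a 5.5-s repetition phase, 7 trials
#' in each of 4 feedback conditions, a 0.55-s whisper threshold and
#' 100-repeat leave-one-out evaluation.
#'
#' @param output_dir Directory for run artifacts.
#' @param cohort_source `"emulate"` (draw a feature table from
#'   [cohort_effect_spec()]) or `"audio"` (synthesize trial audio, then
#'   extract features from the WAV files).
#' @param n_pd,n_ctrl Group sizes.
#' @param n_trials Trials per condition.
#' @param conditions Feedback conditions to run.
#' @param syllable_duration,target_duration,phase_duration Protocol timing
#'   constants, seconds.
#' @param extraction An [extraction_config()].
#' @param effects Effect table for `cohort_source = "emulate"` and for the
#'   audio generator's group differences.
#' @param plan Comparison plan for the statistics stage.
#' @param model_ids Classifier models to evaluate.
#' @param n_repeats Leave-one-out repetitions.
#' @param ntree Random-forest trees.
#' @param stages Character subset of
#'   `c("synth", "extract", "aggregate", "stats", "classify")`.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("pataka_run_"),
                            cohort_source = c("emulate", "audio"),
                            n_pd = 28, n_ctrl = 30,
                            n_trials = 7,
                            conditions = CONDITIONS,
                            syllable_duration = 0.25,
                            target_duration = 3.75,
                            phase_duration = 5.5,
                            extraction = extraction_config(
                              phase_duration = phase_duration),
                            effects = cohort_effect_defaults(),
                            plan = comparison_plan_default(),
                            model_ids = 1:4,
                            n_repeats = 100,
                            ntree = 500,
                            stages = c("synth", "extract", "aggregate",
                                       "stats", "classify"),
                            seed = 1L) {
  cohort_source <- match.arg(cohort_source)
  bad <- setdiff(stages, c("synth", "extract", "aggregate", "stats",
                           "classify"))
  if (length(bad))
    stop_pataka(paste("unknown stages:", paste(bad, collapse = ", ")),
                "pataka_config_error")
  if (n_pd < 1 || n_ctrl < 1 || n_trials < 1)
    stop_pataka("group sizes and n_trials must be positive",
                "pataka_config_error")
  if (is.null(seed)) stop_pataka("a master seed is required",
                                 "pataka_config_error")
  structure(list(
    output_dir = output_dir, cohort_source = cohort_source, n_pd = n_pd,
    n_ctrl = n_ctrl, n_trials = n_trials, conditions = conditions,
    syllable_duration = syllable_duration,
    target_duration = target_duration, phase_duration = phase_duration,
    extraction = extraction, effects = effects, plan = plan,
    model_ids = model_ids, n_repeats = n_repeats, ntree = ntree,
    stages = stages, seed = as.integer(seed)),
    class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be overridden from YAML;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_pataka(paste("unknown config fields:",
                      paste(unknown, collapse = ", ")),
                "pataka_config_error")
  do.call(pipeline_config, raw)
}

# Per-participant, per-condition ground-truth generating parameters for the
# audio-level synthetic cohort: PD participants whisper less reliably,
# start later and drift more, mirroring the group contrasts of the effect
# table qualitatively.
audio_cohort_params <- function(group, condition) {
  pd <- group == "PD"
  list(
    p_whisper = if (condition == "NF") 0
      else if (pd) 0.45 else 0.75,
    onset_mean = if (pd) 0.55 else 0.45,
    jitter_sd = if (pd) 0.035 else 0.015)
}

#' Synthesize a cohort of trial recordings with a manifest
#'
#' Writes one WAV per trial plus `manifest.csv` (participant_id, group,
#' condition, trial_index, wav_path, error_count and ground-truth columns).
#' Group contrasts are built in: PD participants fail to whisper more
#' often, start speaking later and have larger timing jitter.
#'
#' @param dir Output directory (created if needed).
#' @param n_pd,n_ctrl Group sizes.
#' @param n_trials Trials per condition.
#' @param conditions Feedback conditions.
#' @param phase_duration,syllable_duration Protocol timing, seconds.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @return The manifest data.frame, invisibly; also written as CSV.
#' @export
synthesize_cohort_audio <- function(dir, n_pd = 2, n_ctrl = 2,
                                    n_trials = 7,
                                    conditions = CONDITIONS,
                                    phase_duration = 5.5,
                                    syllable_duration = 0.25,
                                    sample_rate = 16000, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- rep(c("PD", "control"), c(n_pd, n_ctrl))
  ids <- sprintf("S%03d", seq_along(groups))
  rows <- list()
  seeds <- derive_seeds(seed, length(ids) * length(conditions) * n_trials)
  k <- 0L
  for (p in seq_along(ids)) {
    for (cond in conditions) {
      pars <- audio_cohort_params(groups[p], cond)
      for (tr in seq_len(n_trials)) {
        k <- k + 1L
        rec_seed <- seeds[k]
        trial <- with_seed(rec_seed, {
          whisper_kept <- cond != "NF" &&
            stats::runif(1) < pars$p_whisper
          onset <- max(0.1, stats::rnorm(1, pars$onset_mean, 0.05))
          rate <- stats::rnorm(1, 4, 0.25)
          n_syll <- floor((phase_duration - onset - 0.1) * rate)
          err <- stats::rpois(1, if (groups[p] == "PD" && cond == "RedF")
            0.45 else 0.2)
          list(spec = trial_synth_spec(
            syllable_duration = min(syllable_duration, 0.9 / rate),
            n_syllables = n_syll, syllabic_rate = rate,
            onset_delay = onset, rate_jitter_sd = pars$jitter_sd,
            voiced = !whisper_kept, phase_duration = phase_duration,
            sample_rate = sample_rate,
            seed = stats::runif(1, 1, .Machine$integer.max)),
            error_count = err)
        })
        rec <- synthesize_trial(trial$spec)
        wav <- file.path(dir, sprintf("%s_%s_%02d.wav", ids[p], cond, tr))
        write_wav(rec$samples, sample_rate, wav)
        rows[[k]] <- data.frame(
          participant_id = ids[p], group = groups[p], condition = cond,
          trial_index = tr, wav_path = wav, error_count = trial$error_count,
          age = NA_real_,
          gt_onset = rec$ground_truth$onset, gt_rate = rec$ground_truth$rate,
          gt_voiced = rec$ground_truth$voiced,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run the screening pipeline end to end
#'
#' Executes the enabled stages in order — synthesize, extract, aggregate,
#' stats, classify — writing the cohort table, comparison results,
#' classifier reports and a reproducibility manifest (seed, config JSON,
#' config hash, package version, artifact list) to `config$output_dir`.
#' Per-trial extraction failures are logged and skipped; the run continues.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_run` with the in-memory artifacts
#'   (`cohort`, `comparison`, `suite`, `manifest`, `log`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seeds <- derive_seeds(config$seed, 4)
  artifacts <- character(0)
  cohort <- NULL; comparison <- NULL; suite <- NULL

  if (config$cohort_source == "audio") {
    audio_dir <- file.path(config$output_dir, "audio")
    manifest_path <- file.path(audio_dir, "manifest.csv")
    if ("synth" %in% config$stages) {
      say("synth: %d+%d participants x %d conditions x %d trials",
          config$n_pd, config$n_ctrl, length(config$conditions),
          config$n_trials)
      synthesize_cohort_audio(
        audio_dir, config$n_pd, config$n_ctrl, config$n_trials,
        config$conditions, config$phase_duration,
        config$syllable_duration, seed = seeds[1])
      artifacts <- c(artifacts, manifest_path)
    }
    if (any(c("extract", "aggregate") %in% config$stages)) {
      manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
      say("extract: measuring %d trials", nrow(manifest))
      measurements <- vector("list", nrow(manifest))
      for (i in seq_len(nrow(manifest))) {
        measurements[[i]] <- tryCatch({
          wav <- read_wav(manifest$wav_path[i])
          measure_trial(wav, manifest$error_count[i], config$extraction)
        }, error = function(e) {
          say("extract: trial %s/%s/%s failed: %s",
              manifest$participant_id[i], manifest$condition[i],
              manifest$trial_index[i], conditionMessage(e))
          NULL
        })
      }
      ok <- !vapply(measurements, is.null, logical(1))
      cohort <- build_cohort_table(manifest[ok, , drop = FALSE],
                                   measurements[ok],
                                   config$phase_duration)
    }
  } else if (any(c("synth", "aggregate") %in% config$stages)) {
    say("aggregate: emulating %d+%d participant feature table",
        config$n_pd, config$n_ctrl)
    cohort <- emulate_cohort(cohort_effect_spec(
      effects = config$effects, n_pd = config$n_pd,
      n_ctrl = config$n_ctrl, seed = seeds[1]))
  }

  if (!is.null(cohort)) {
    cohort_path <- file.path(config$output_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_path)
    artifacts <- c(artifacts, cohort_path)
  }

  if ("stats" %in% config$stages && !is.null(cohort)) {
    say("stats: %d planned comparisons", nrow(config$plan))
    comparison <- withCallingHandlers(
      compare_groups(cohort, config$plan),
      warning = function(w) {
        say("stats: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    comp_path <- file.path(config$output_dir, "comparison.csv")
    utils::write.csv(as.data.frame(comparison), comp_path,
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(comparison),
                         file.path(config$output_dir, "comparison.json"),
                         digits = NA)
    artifacts <- c(artifacts, comp_path,
                   file.path(config$output_dir, "comparison.json"))
  }

  if ("classify" %in% config$stages && !is.null(cohort)) {
    say("classify: models %s, %d repeats",
        paste(config$model_ids, collapse = ","), config$n_repeats)
    specs <- lapply(seq_along(config$model_ids), function(i)
      model_spec(config$model_ids[i], n_repeats = config$n_repeats,
                 ntree = config$ntree,
                 seed = derive_seeds(seeds[3], length(config$model_ids))[i]))
    available <- vapply(specs, function(s)
      all(s$features %in% names(cohort)), logical(1))
    suite <- run_model_suite(cohort, specs[available])
    report_path <- file.path(config$output_dir, "classifier_report.csv")
    utils::write.csv(as.data.frame(suite), report_path, row.names = FALSE)
    artifacts <- c(artifacts, report_path)
  }

  config_path <- file.path(config$output_dir, "config.json")
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config),
                                              c("extraction"))],
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  writeLines(cfg_json, config_path)
  run_manifest <- list(
    seed = config$seed,
    config_file = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    package_version = as.character(utils::packageVersion("pataka")),
    artifacts = basename(artifacts))
  manifest_path <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, manifest_path, auto_unbox = TRUE)
  writeLines(log_lines, log_path)
  structure(list(cohort = cohort, comparison = comparison, suite = suite,
                 manifest = run_manifest, log = log_lines,
                 output_dir = config$output_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pataka pipeline run ->", x$output_dir, "\n")
  cat("artifacts:", paste(x$manifest$artifacts, collapse = ", "), "\n")
  if (!is.null(x$comparison)) summary(x$comparison)
  if (!is.null(x$suite)) print(x$suite)
  invisible(x)
}
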