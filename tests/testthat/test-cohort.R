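make_measurement <- function(whis = FALSE, onset = 0.5, f_max = 4,
                             errors = 0L, speech = TRUE, spectrum = NULL) {
  structure(list(whis = whis, voiced_duration = if (whis) 0 else 5,
                 onset = onset, spectrum = spectrum, f_max = f_max,
                 speech_detected = speech, error_count = as.integer(errors)),
            class = "trial_measurements")
}

test_that("measure_trial integrates segmentation and rhythm features", {
  rec <- synthesize_trial(trial_synth_spec(onset_delay = 0.5, voiced = TRUE,
                                           seed = 61))
  m <- measure_trial(rec, error_count = 0L)
  expect_false(m$whis)
  expect_lt(abs(m$onset - 0.5), 0.025)
  expect_equal(m$f_max, 4.0, tolerance = 0.2 / 4)
  expect_equal(m$error_count, 0L)
  expect_true(m$speech_detected)

  wm <- measure_trial(synthesize_trial(trial_synth_spec(voiced = FALSE,
                                                        seed = 62)))
  expect_true(wm$whis)

  silent <- measure_trial(list(samples = numeric(88000),
                               sample_rate = 16000))
  expect_true(silent$whis)
  expect_true(is.na(silent$onset))
  expect_true(is.na(silent$f_max))
  expect_false(silent$speech_detected)
})

test_that("condition features aggregate per the five-parameter definitions", {
  ms <- c(lapply(1:3, function(i) make_measurement(whis = TRUE)),
          lapply(1:4, function(i) make_measurement()))
  cf <- condition_features(ms, phase_duration = 5.5)
  expect_equal(cf$pct_whispered, 100 * 3 / 7)

  ms2 <- list(make_measurement(onset = 0.4),
              make_measurement(onset = 0.6),
              make_measurement(onset = NA_real_, f_max = NA_real_,
                               speech = FALSE))
  cf2 <- condition_features(ms2, phase_duration = 5.5)
  expect_equal(cf2$mean_rt, 0.5)
  expect_equal(cf2$n_trials_used$rt, 2)

  # errors per second over trials with detected speech only
  ms3 <- list(make_measurement(errors = 2L), make_measurement(errors = 1L),
              make_measurement(errors = 5L, speech = FALSE,
                               onset = NA_real_, f_max = NA_real_))
  cf3 <- condition_features(ms3, phase_duration = 5.5)
  expect_equal(cf3$errors_per_sec, 3 / (2 * 5.5))

  # identical trials give consistency exactly 1
  sp <- trial_spectrum(trial_synth_spec(seed = 63))
  ms4 <- lapply(1:7, function(i) make_measurement(spectrum = sp))
  expect_equal(condition_features(ms4)$rhythm_consistency, 1.0)

  expect_error(condition_features(list()), "at least one")
})

test_that("all-voiced and all-whispered participants hit 0 and 100 percent", {
  all_v <- lapply(1:7, function(i) make_measurement(whis = FALSE))
  all_w <- lapply(1:7, function(i) make_measurement(whis = TRUE))
  expect_equal(condition_features(all_v)$pct_whispered, 0)
  expect_equal(condition_features(all_w)$pct_whispered, 100)
})

test_that("cohort table assembly validates keys and fills blocks", {
  manifest <- expand.grid(trial_index = 1:2, condition = c("NF", "RedF"),
                          participant_id = c("P1", "P2"),
                          stringsAsFactors = FALSE)
  manifest$group <- ifelse(manifest$participant_id == "P1", "PD", "control")
  ms <- lapply(seq_len(nrow(manifest)), function(i) make_measurement())
  tab <- build_cohort_table(manifest, ms)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("whis_NF", "RhyStrCons_RedF") %in% names(tab)))

  # a participant with a missing condition gets an NA block, others intact
  m2 <- manifest[!(manifest$participant_id == "P2" &
                     manifest$condition == "RedF"), ]
  tab2 <- build_cohort_table(m2, ms[seq_len(nrow(m2))])
  expect_true(is.na(tab2$whis_RedF[tab2$participant_id == "P2"]))
  expect_false(is.na(tab2$whis_NF[tab2$participant_id == "P2"]))

  dup <- rbind(manifest, manifest[1, ])
  expect_error(build_cohort_table(dup, c(ms, ms[1])),
               "duplicate trial key: P1/NF/1")
})

test_that("cohort CSV round-trips numerically", {
  tab <- emulate_cohort(cohort_effect_spec(seed = 17))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  for (col in num)
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  expect_identical(as.character(back$group), as.character(tab$group))
})
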