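test_that("target stimulus has the protocol's duration and syllable count", {
  tgt <- synthesize_target_audio(voiced = TRUE)
  expect_equal(length(tgt$samples) / tgt$sample_rate, 3.75)
  # 15 amplitude bursts: count envelope maxima above half-max
  env <- compute_envelope(tgt$samples, tgt$sample_rate)
  sp <- envelope_spectrum(env)  # smoothing path exercised separately
  lp <- signal::butter(4, 30 / (tgt$sample_rate / 2), type = "low")
  sm <- signal::filtfilt(lp, env$samples)
  above <- sm > max(sm) / 2
  expect_equal(sum(rle(above)$values), 15)
  expect_equal(syllabic_rate(sp), 4.0, tolerance = 0.2 / 4.0)
})

test_that("whispered target is classified as whispered by the pipeline", {
  tgt <- synthesize_target_audio(voiced = FALSE, seed = 4)
  vr <- voiced_duration(tgt$samples, tgt$sample_rate)
  expect_true(classify_whisper(vr$voiced_duration, 0.375))
})

test_that("synthesized trials echo their ground truth and are reproducible", {
  spec <- trial_synth_spec(syllabic_rate = 4, rate_jitter_sd = 0,
                           onset_delay = 0.5, seed = 21)
  rec <- synthesize_trial(spec)
  expect_equal(rec$ground_truth$onset, 0.5)
  expect_equal(rec$ground_truth$rate, 4)
  expect_length(rec$samples, round(5.5 * 16000))
  rec2 <- synthesize_trial(spec)
  expect_identical(rec$samples, rec2$samples)

  # realized mean syllable period stays near 1/rate under jitter
  sj <- trial_synth_spec(rate_jitter_sd = 0.02, seed = 22)
  rj <- synthesize_trial(sj)
  on <- rj$ground_truth$syllable_onsets
  expect_lt(abs(mean(diff(on)) - 0.25), 3 * 0.02)
})

test_that("trial specs violating their invariants are rejected by name", {
  expect_error(trial_synth_spec(syllable_duration = 0), "syllable_duration")
  expect_error(trial_synth_spec(syllabic_rate = -1), "syllabic_rate")
  expect_error(trial_synth_spec(n_syllables = 40, syllabic_rate = 4,
                                onset_delay = 1, phase_duration = 5.5),
               "phase_duration")
  expect_error(trial_synth_spec(sample_rate = 4000), "sample_rate")
})

test_that("a 2.5 Hz trial yields a 2.5 Hz envelope peak via the pipeline", {
  sp <- trial_spectrum(trial_synth_spec(syllabic_rate = 2.5,
                                        n_syllables = 12, seed = 3))
  expect_equal(syllabic_rate(sp), 2.5, tolerance = 0.2 / 2.5)
})

test_that("maskers have the required rhythmic structure", {
  noise <- synthesize_masker("noise", 5.5, seed = 2)
  expect_length(noise, round(5.5 * 16000))
  spn <- envelope_spectrum(compute_envelope(noise, 16000))
  # white noise: no dominant modulation peak in 1-10 Hz
  expect_lt(max(spn$power) / stats::median(spn$power), 100)

  exo <- synthesize_masker("exogenous_speech", 5.5, seed = 2)
  spe <- envelope_spectrum(compute_envelope(exo, 16000))
  expect_equal(syllabic_rate(spe), 4.0, tolerance = 0.2 / 4.0)
  expect_gt(max(spe$power) / stats::median(spe$power), 100)

  expect_error(synthesize_masker("noise", duration = 0), "duration")
  expect_error(synthesize_masker("chirp"))
})

test_that("emulated cohorts honor the effect spec", {
  tab <- emulate_cohort(cohort_effect_spec(seed = 5))
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 58)
  expect_equal(sum(tab$group == "PD"), 28)
  # zero-SD spec makes every PD row equal to the PD means
  eff <- cohort_effect_defaults()
  eff$sd <- 0
  t0 <- emulate_cohort(cohort_effect_spec(effects = eff, seed = 1))
  expect_true(all(t0$whis_MF[t0$group == "PD"] == 43))
  expect_true(all(t0$SpErr_RedF[t0$group == "control"] == 0.022))
  # reproducibility and group-size validation
  expect_identical(emulate_cohort(cohort_effect_spec(seed = 9)),
                   emulate_cohort(cohort_effect_spec(seed = 9)))
  expect_error(cohort_effect_spec(n_pd = 0), "positive")
})

test_that("emulated features never leave their admissible ranges", {
  eff <- cohort_effect_defaults()
  eff$sd <- eff$sd * 4  # stress the censoring
  tab <- emulate_cohort(cohort_effect_spec(effects = eff, n_pd = 2500,
                                           n_ctrl = 2500, seed = 12))
  whis <- unlist(tab[grep("^whis_", names(tab))])
  cons <- unlist(tab[grep("^RhyStrCons_", names(tab))])
  pos <- unlist(tab[grep("^(SpErr|RT|Rate)_", names(tab))])
  expect_true(all(whis >= 0 & whis <= 100))
  expect_true(all(cons >= -1 & cons <= 1))
  expect_true(all(pos >= 0))
})

test_that("sample means of the emulated cohort track the configured means", {
  tab <- emulate_cohort(cohort_effect_spec(seed = 31))
  m <- mean(tab$whis_MF[tab$group == "PD"])
  se <- 33 / sqrt(28)
  expect_lt(abs(m - 43), 3 * se)
})
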