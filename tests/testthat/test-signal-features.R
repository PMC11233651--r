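test_that("envelope recovers the amplitude of a pure sinusoid", {
  fs <- 8000
  t <- seq(0, 1, by = 1 / fs)
  x <- 0.7 * sin(2 * pi * 440 * t)
  env <- compute_envelope(x, fs)
  core <- env$samples[(0.1 * fs):(0.9 * fs)]  # away from edges
  expect_true(all(abs(core - 0.7) < 0.007))
  expect_true(all(env$samples >= 0))
  expect_length(env$samples, length(x))
})

test_that("envelope of silence is zero and bad input is rejected", {
  env <- compute_envelope(numeric(1000), 8000)
  expect_true(all(env$samples == 0))
  expect_error(compute_envelope(numeric(0), 8000), "non-empty")
  expect_error(compute_envelope(c(1, NA, 2), 8000), "non-finite")
})

test_that("burst-modulated noise has one envelope maximum per burst", {
  rec <- synthesize_trial(trial_synth_spec(voiced = FALSE, n_syllables = 20,
                                           onset_delay = 0.5, seed = 14))
  env <- compute_envelope(rec$samples, rec$sample_rate)
  lp <- signal::butter(4, 30 / (rec$sample_rate / 2), type = "low")
  sm <- signal::filtfilt(lp, env$samples)
  expect_equal(sum(rle(sm > max(sm) / 2)$values), 20)
})

test_that("envelope spectrum localizes a known modulation frequency", {
  fs <- 1000
  t <- seq(0, 5.5, by = 1 / fs)[-1]
  env <- structure(list(samples = 1 + cos(2 * pi * 3 * t), sample_rate = fs),
                   class = "envelope")
  sp <- envelope_spectrum(env, smooth = FALSE)
  expect_equal(syllabic_rate(sp), 3.0, tolerance = sp$bin_width / 3)
  expect_lte(sp$bin_width, 0.2)

  flat <- structure(list(samples = rep(2, 5500), sample_rate = fs),
                    class = "envelope")
  spf <- envelope_spectrum(flat, smooth = FALSE)
  expect_lt(max(spf$power), 1e-12)
  expect_error(syllabic_rate(spf), "no rhythmic peak")
  expect_error(envelope_spectrum(env, band = c(1, 600)), "Nyquist")
})

test_that("syllabic rate is the argmax with lower-frequency tie-break", {
  sp <- structure(list(freq = c(2, 3.74, 5, 6), power = c(1, 9, 9, 2),
                       band = c(1, 10), bin_width = 1),
                  class = "envelope_spectrum")
  expect_equal(syllabic_rate(sp), 3.74)
  expect_error(syllabic_rate(structure(
    list(freq = 1:3, power = numeric(3), band = c(1, 10), bin_width = 1),
    class = "envelope_spectrum")), "no rhythmic peak")
})

test_that("rhythm consistency matches its definition and bounds", {
  sp <- trial_spectrum(trial_synth_spec(seed = 5))
  expect_equal(rhythm_consistency(rep(list(sp), 7)), 1.0)

  # two exactly anti-correlated power vectors
  base <- sp
  flipped <- sp
  flipped$power <- max(sp$power) + min(sp$power) - sp$power
  expect_equal(rhythm_consistency(list(base, flipped)), -1.0)

  expect_error(rhythm_consistency(list(sp)), "at least two")
  short <- sp; short$freq <- sp$freq + 0.1
  expect_error(rhythm_consistency(list(sp, short)), "identical frequency")
  flat <- sp; flat$power <- rep(1, length(sp$power))
  expect_error(rhythm_consistency(list(sp, flat)), "degenerate")
})

test_that("consistency equals the brute-force pairwise mean and is
           permutation invariant", {
  spectra <- lapply(1:5, function(k)
    trial_spectrum(trial_synth_spec(rate_jitter_sd = 0.03, seed = 40 + k)))
  expect_equal(rhythm_consistency(spectra),
               pairwise_mean_consistency(spectra))
  perm <- spectra[c(3, 1, 5, 2, 4)]
  expect_equal(rhythm_consistency(perm), rhythm_consistency(spectra))
  r <- rhythm_consistency(spectra)
  expect_true(r >= -1 && r <= 1)
})

test_that("amplitude scaling leaves rate and consistency unchanged", {
  rec <- synthesize_trial(trial_synth_spec(seed = 8))
  sp1 <- envelope_spectrum(compute_envelope(rec$samples, rec$sample_rate))
  sp2 <- envelope_spectrum(compute_envelope(3.7 * rec$samples,
                                            rec$sample_rate))
  expect_equal(syllabic_rate(sp1), syllabic_rate(sp2))
  other <- trial_spectrum(trial_synth_spec(rate_jitter_sd = 0.02, seed = 9))
  expect_equal(rhythm_consistency(list(sp1, other)),
               rhythm_consistency(list(sp2, other)), tolerance = 1e-10)
  # envelope itself scales linearly
  e1 <- compute_envelope(rec$samples, rec$sample_rate)
  e2 <- compute_envelope(3.7 * rec$samples, rec$sample_rate)
  expect_equal(e2$samples, 3.7 * e1$samples, tolerance = 1e-9)
})
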