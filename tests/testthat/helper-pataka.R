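# Shared fixtures and independent oracles for the test suite.

# Envelope spectrum of a synthesized trial, via the full pipeline.
trial_spectrum <- function(spec) {
  rec <- synthesize_trial(spec)
  envelope_spectrum(compute_envelope(rec$samples, rec$sample_rate))
}

# Exhaustive Mann-Whitney oracle: enumerate all C(n_a + n_b, n_a) group
# labelings of the pooled sample; U = #(a > b) pairs (+ 1/2 per tie), exact
# two-sided p = 2 * min(P(U <= u_obs), P(U >= u_obs)) capped at 1.
enumerate_mw <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y)
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p = p)
}

# Pair-counting rank-biserial oracle (explicit double loop).
enumerate_rb <- function(a, b) {
  fav <- 0; unf <- 0
  for (ai in a) for (bi in b) {
    if (bi > ai) fav <- fav + 1
    if (bi < ai) unf <- unf + 1
  }
  (fav - unf) / (length(a) * length(b))
}

# Brute-force mean over all unordered spectrum pairs.
pairwise_mean_consistency <- function(spectra) {
  n <- length(spectra)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, stats::cor(spectra[[i]]$power, spectra[[j]]$power))
  mean(vals)
}

# Sample-level silence oracle for short toy signals: frame-wise threshold
# on |x| maxima with simple run merging, independent of the package's
# RMS/dB implementation.
oracle_intervals <- function(x, fs, thr_rel = 10^(-25 / 20),
                             min_silent = 0.1, min_sounding = 0.05,
                             frame = 0.025, hop = 0.005) {
  fl <- round(frame * fs); hl <- round(hop * fs)
  starts <- seq(1, length(x) - fl + 1, by = hl)
  level <- sapply(starts, function(s) sqrt(mean(x[s:(s + fl - 1)]^2)))
  sounding <- level > max(level) * thr_rel & level > 0
  r <- rle(sounding)
  if (length(r$lengths) > 2)
    for (i in 2:(length(r$lengths) - 1))
      if (!r$values[i] && r$lengths[i] * hop < min_silent) r$values[i] <- TRUE
  sounding <- inverse.rle(r); r <- rle(sounding)
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] * hop < min_sounding) r$values[i] <- FALSE
  sounding <- inverse.rle(r); r <- rle(sounding)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = (starts[starts_i[keep]] - 1) / fs,
             end = pmin((starts[ends_i[keep]] - 1 + fl) / fs, length(x) / fs))
}

# A small emulated cohort where one feature separates the groups fully.
separable_cohort <- function(seed = 1) {
  tab <- emulate_cohort(cohort_effect_spec(seed = seed))
  with_sep <- within(as.data.frame(tab), RhyStrCons_NF <- ifelse(
    group == "PD", 0.2, 0.9))
  class(with_sep) <- class(tab)
  with_sep
}
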