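#' Default group-level effect sizes for cohort emulation
#'
#' Group means and standard deviations of the five screening parameters in
#' the conditions where they are analysed: percentage of whispered trials in
#' the three whisper conditions, and errors per second, reaction time,
#' syllabic rate and rhythmic consistency in the Normal and Reduced feedback
#' conditions (11 parameter/condition cells per group).
#'
#' @return Data.frame with columns `parameter`, `condition`, `group`,
#'   `mean`, `sd`.
#' @export
cohort_effect_defaults <- function() {
  cells <- rbind(
    # parameter, condition, PD mean, PD sd, control mean, control sd
    c("whis",       "RedF", 66,    38,    79,    37),
    c("whis",       "MF",   43,    33,    72,    38),
    c("whis",       "RepF", 36,    38,    70,    41),
    c("SpErr",      "NF",   0.039, 0.069, 0.044, 0.126),
    c("SpErr",      "RedF", 0.082, 0.092, 0.022, 0.076),
    c("RT",         "NF",   0.59,  0.20,  0.49,  0.15),
    c("RT",         "RedF", 0.50,  0.18,  0.39,  0.14),
    c("Rate",       "NF",   3.74,  0.81,  4.05,  0.71),
    c("Rate",       "RedF", 3.56,  0.87,  3.94,  0.68),
    c("RhyStrCons", "NF",   0.70,  0.16,  0.82,  0.13),
    c("RhyStrCons", "RedF", 0.81,  0.11,  0.85,  0.13))
  data.frame(
    parameter = rep(cells[, 1], 2),
    condition = rep(cells[, 2], 2),
    group = rep(c("PD", "control"), each = nrow(cells)),
    mean = as.numeric(c(cells[, 3], cells[, 5])),
    sd = as.numeric(c(cells[, 4], cells[, 6])),
    stringsAsFactors = FALSE)
}

# Admissible range (censoring bounds) of each parameter.
parameter_range <- function(parameter) {
  switch(parameter,
         whis = c(0, 100),
         RhyStrCons = c(-1, 1),
         SpErr = , RT = , Rate = c(0, Inf),
         c(-Inf, Inf))
}

#' Specification of an emulated cohort
#'
#' @param effects Data.frame as returned by [cohort_effect_defaults()]; one
#'   row per (parameter, condition, group) with `mean` and `sd`.
#' @param n_pd,n_ctrl Group sizes (both > 0); defaults 28 and 30.
#' @param age_pd,age_ctrl Length-4 numeric `c(mean, sd, min, max)` of each
#'   group's age distribution (years).
#' @param seed Integer seed.
#' @return List of class `cohort_effect_spec`.
#' @export
cohort_effect_spec <- function(effects = cohort_effect_defaults(),
                               n_pd = 28, n_ctrl = 30,
                               age_pd = c(68.6, 11, 38, 88),
                               age_ctrl = c(66, 9, 46, 93),
                               seed = NULL) {
  if (n_pd < 1 || n_ctrl < 1)
    stop_pataka("group sizes must be positive", "pataka_spec_error")
  need <- c("parameter", "condition", "group", "mean", "sd")
  if (!all(need %in% names(effects)))
    stop_pataka(paste("effects must have columns:",
                      paste(need, collapse = ", ")), "pataka_spec_error")
  if (any(effects$sd < 0))
    stop_pataka("effect SDs must be >= 0", "pataka_spec_error")
  structure(list(effects = effects, n_pd = as.integer(n_pd),
                 n_ctrl = as.integer(n_ctrl), age_pd = age_pd,
                 age_ctrl = age_ctrl, seed = seed),
            class = "cohort_effect_spec")
}

#' Emulate a participant-level cohort feature table
#'
#' Draws each participant's feature values independently from censored
#' normal distributions with the group means/SDs of `spec`: draws beyond a
#' feature's admissible range are set to the bound (percentages to
#' \[0, 100\], consistency to \[-1, 1\], rates/times/error rates to >= 0).
#' Censoring, rather than renormalized truncation, keeps the sample means
#' at the configured means and reproduces the pile-up at the bounds that
#' bounded features (e.g. percentages of seven trials) show in real
#' cohorts. The result is a statistical stand-in for a real cohort table
#' with the same group-level structure.
#'
#' @param spec A [cohort_effect_spec()].
#' @return A `cohort_table` with `n_pd + n_ctrl` rows.
#' @export
emulate_cohort <- function(spec = cohort_effect_spec()) {
  if (!inherits(spec, "cohort_effect_spec"))
    stop_pataka("spec must be a cohort_effect_spec", "pataka_spec_error")
  with_seed(spec$seed, {
    n <- c(PD = spec$n_pd, control = spec$n_ctrl)
    tab <- data.frame(
      participant_id = sprintf("S%03d", seq_len(sum(n))),
      group = factor(rep(names(n), n), levels = c("PD", "control")),
      stringsAsFactors = FALSE)
    age <- list(PD = spec$age_pd, control = spec$age_ctrl)
    tab$age <- unlist(lapply(names(n), function(g)
      rcensnorm(n[[g]], age[[g]][1], age[[g]][2], age[[g]][3],
                 age[[g]][4])))
    eff <- spec$effects
    for (i in seq_len(nrow(eff))) {
      col <- feature_column(eff$parameter[i], eff$condition[i])
      if (!col %in% names(tab)) tab[[col]] <- NA_real_
      rng <- parameter_range(eff$parameter[i])
      sel <- tab$group == eff$group[i]
      tab[[col]][sel] <- rcensnorm(sum(sel), eff$mean[i], eff$sd[i],
                                    rng[1], rng[2])
    }
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
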