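#' Mann-Whitney U test for two independent samples
#'
#' U counts the pairs where `a` exceeds `b` (ties contribute 1/2). The
#' two-sided p value is exact when the combined sample size is at most 20
#' and there are no ties, and uses the normal approximation with continuity
#' and tie corrections otherwise.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop_pataka("both samples must be non-empty", "pataka_input_error")
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop_pataka("both samples must contain non-missing values",
                "pataka_input_error")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1))
  has_ties <- anyDuplicated(pooled) > 0
  exact <- (length(a) + length(b) <= 20) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Rank-biserial correlation effect size
#'
#' The difference between the proportions of favorable and unfavorable
#' cross-group pairs; ties contribute to neither. With the default
#' direction, a pair is favorable when the `b` value exceeds the `a` value,
#' so with `a` = PD and `b` = controls a positive r means controls tend to
#' score higher. An r of 0.38 corresponds to favorable evidence outweighing
#' unfavorable by 69\% to 31\%.
#'
#' @param a,b Numeric samples.
#' @param direction `"b_greater"` (default: favorable = b > a) or
#'   `"a_greater"`.
#' @return r in \[-1, 1\].
#' @export
rank_biserial <- function(a, b, direction = c("b_greater", "a_greater")) {
  direction <- match.arg(direction)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop_pataka("both samples must be non-empty", "pataka_input_error")
  cmp <- outer(b, a, `-`)
  r <- (sum(cmp > 0) - sum(cmp < 0)) / (length(a) * length(b))
  if (direction == "a_greater") r <- -r
  r
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values (q values) with enforced monotonicity, capped
#' at 1.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Vector of q values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_pataka("p values must lie in [0, 1]", "pataka_input_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Default group-comparison plan
#'
#' Eleven tests: percentage of whispered trials in the three conditions
#' that require whispering (RedF, MF, RepF), and errors per second,
#' reaction time, syllabic rate and rhythmic consistency in the Normal and
#' Reduced feedback conditions — the conditions where the groups do not
#' differ in the number of spoken-aloud trials.
#'
#' @return Data.frame with columns `parameter` and `condition`.
#' @export
comparison_plan_default <- function() {
  data.frame(
    parameter = c("whis", "whis", "whis",
                  rep(c("SpErr", "RT", "Rate", "RhyStrCons"), each = 2)),
    condition = c("RedF", "MF", "RepF", rep(c("NF", "RedF"), 4)),
    stringsAsFactors = FALSE)
}

#' Nonparametric group comparison of the screening parameters
#'
#' Runs a Mann-Whitney test, rank-biserial effect size and group summary
#' statistics for every (parameter, condition) pair of the plan, adjusting
#' p values across the whole family with the Benjamini-Hochberg false
#' discovery rate. Positive r means controls score higher than the PD
#' group.
#'
#' @param table A `cohort_table` with both groups present.
#' @param plan Data.frame of `parameter`, `condition` pairs
#'   (default [comparison_plan_default()]).
#' @param alpha Significance threshold recorded in the result.
#' @return Object of class `group_comparison`: a data.frame with one row
#'   per test (`parameter`, `condition`, `n_pd`, `n_ctrl`, `mean_pd`,
#'   `sd_pd`, `mean_ctrl`, `sd_ctrl`, `U`, `p_raw`, `p_fdr`,
#'   `r_rank_biserial`, `significant`).
#' @export
compare_groups <- function(table, plan = comparison_plan_default(),
                           alpha = 0.05) {
  stopifnot(is.data.frame(table))
  if (length(unique(stats::na.omit(as.character(table$group)))) < 2)
    stop_pataka("both groups must be present", "pataka_input_error")
  pd <- table$group == "PD"
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    col <- feature_column(plan$parameter[i], plan$condition[i])
    if (!col %in% names(table)) {
      warning(sprintf("feature column '%s' missing; test skipped", col))
      next
    }
    x_pd <- table[[col]][pd]
    x_ct <- table[[col]][!pd]
    mw <- mann_whitney_u(x_pd, x_ct)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = plan$parameter[i], condition = plan$condition[i],
      n_pd = sum(!is.na(x_pd)), n_ctrl = sum(!is.na(x_ct)),
      mean_pd = mean(x_pd, na.rm = TRUE), sd_pd = stats::sd(x_pd, na.rm = TRUE),
      mean_ctrl = mean(x_ct, na.rm = TRUE),
      sd_ctrl = stats::sd(x_ct, na.rm = TRUE),
      U = mw$U, p_raw = mw$p,
      r_rank_biserial = rank_biserial(x_pd, x_ct),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop_pataka("no plan feature present in the table", "pataka_input_error")
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out$significant <- out$p_fdr < alpha
  out <- out[c("parameter", "condition", "n_pd", "n_ctrl", "mean_pd",
               "sd_pd", "mean_ctrl", "sd_ctrl", "U", "p_raw", "p_fdr",
               "r_rank_biserial", "significant")]
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Mann-Whitney, BH-FDR), PD vs control\n")
  cat(sprintf("alpha = %g; positive r: controls > PD\n\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  df$mean_pd <- sprintf("%.3g (%.2g)", df$mean_pd, df$sd_pd)
  df$mean_ctrl <- sprintf("%.3g (%.2g)", df$mean_ctrl, df$sd_ctrl)
  df$p_raw <- sprintf("%.4f", df$p_raw)
  df$p_fdr <- sprintf("%.4f", df$p_fdr)
  df$r_rank_biserial <- sprintf("%+.2f", df$r_rank_biserial)
  df$sig <- ifelse(df$significant, "*", "")
  print(df[c("parameter", "condition", "mean_pd", "mean_ctrl", "U",
             "p_raw", "p_fdr", "r_rank_biserial", "sig")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  cat(sprintf("%d tests, %d significant at FDR < %g:\n", nrow(object),
              sum(object$significant), attr(object, "alpha")))
  sig <- object[object$significant, c("parameter", "condition", "p_fdr",
                                      "r_rank_biserial")]
  if (nrow(sig)) print(as.data.frame(sig), row.names = FALSE)
  invisible(object)
}
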