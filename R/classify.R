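#' Feature sets of the four screening classifier models
#'
#' Model 1 uses the five parameters that separate the groups (whispered-
#' trial percentage in Replaced and Masked feedback, errors per second and
#' reaction time in Reduced feedback, rhythmic consistency in Normal
#' feedback). Model 2 drops the Masked whisper percentage, Model 3 drops
#' the Replaced one, and Model 4 is Model 2 plus age.
#'
#' @param model_id Integer 1-4.
#' @return Character vector of cohort-table column names.
#' @export
model_features <- function(model_id) {
  m1 <- c("whis_RepF", "whis_MF", "SpErr_RedF", "RT_RedF", "RhyStrCons_NF")
  switch(as.character(model_id),
         "1" = m1,
         "2" = setdiff(m1, "whis_MF"),
         "3" = setdiff(m1, "whis_RepF"),
         "4" = c(setdiff(m1, "whis_MF"), "age"),
         stop_pataka("model_id must be 1, 2, 3 or 4", "pataka_spec_error"))
}

#' Specification of one classifier evaluation
#'
#' @param model_id Integer 1-4 selecting a [model_features()] set, or any
#'   id if `features` is given explicitly.
#' @param features Character vector of feature columns (default: the
#'   Table-style set for `model_id`).
#' @param n_repeats Number of leave-one-out repetitions to average
#'   (default 100; repeats differ only in the forest's internal
#'   randomness).
#' @param ntree,mtry Random-forest hyperparameters (defaults: 500 trees,
#'   `floor(sqrt(p))` candidate features per split).
#' @param seed Integer master seed.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(model_id, features = model_features(model_id),
                       n_repeats = 100, ntree = 500, mtry = NULL,
                       seed = NULL) {
  stopifnot(length(features) >= 1, n_repeats >= 1, ntree >= 1)
  structure(list(model_id = model_id, features = features,
                 n_repeats = as.integer(n_repeats),
                 ntree = as.integer(ntree), mtry = mtry, seed = seed),
            class = "model_spec")
}

#' Accuracy, sensitivity and specificity of predicted labels
#'
#' PD is the positive class: sensitivity is the proportion of PD
#' participants detected, specificity the proportion of controls correctly
#' classified. All metrics are percentages.
#'
#' @param y_true,y_pred Equal-length label vectors with levels `PD` and
#'   `control`; `y_true` must contain both classes.
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_pataka("label vectors must have equal length", "pataka_input_error")
  if (length(unique(y_true)) < 2)
    stop_pataka("y_true must contain both classes", "pataka_input_error")
  pos <- y_true == "PD"
  tp <- sum(pos & y_pred == "PD"); fn <- sum(pos & y_pred != "PD")
  tn <- sum(!pos & y_pred == "control"); fp <- sum(!pos & y_pred != "control")
  c(accuracy = 100 * (tp + tn) / length(y_true),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

# Median imputation: medians computed on the training fold only, applied to
# both the training fold and the held-out row.
impute_fold <- function(train, test, features) {
  for (f in features) {
    med <- stats::median(train[[f]], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    train[[f]][is.na(train[[f]])] <- med
    test[[f]][is.na(test[[f]])] <- med
  }
  list(train = train, test = test)
}

#' Repeated leave-one-out evaluation of a random-forest screener
#'
#' For each repeat, every participant is held out once: a random forest is
#' trained on all others and predicts the held-out participant; accuracy,
#' sensitivity and specificity are computed from the pooled leave-one-out
#' predictions, then averaged across repeats. Repeats differ only in the
#' forest's internal randomness. Missing features are median-imputed within
#' each training fold.
#'
#' @param table A `cohort_table` with >= 2 participants per group.
#' @param spec A [model_spec()].
#' @return Object of class `classifier_report`: `model_id`, `features`,
#'   `metrics` (mean over repeats), `metrics_sd`, `per_repeat` data.frame,
#'   `confusion` (mean counts), `n_pd`, `n_ctrl`, `n_repeats`.
#' @export
loo_evaluate <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(table))
  missing_cols <- setdiff(spec$features, names(table))
  if (length(missing_cols))
    stop_pataka(paste("features missing from table:",
                      paste(missing_cols, collapse = ", ")),
                "pataka_input_error")
  y <- factor(as.character(table$group), levels = c("PD", "control"))
  if (any(is.na(y)) || length(unique(y)) < 2 || min(base::table(y)) < 2)
    stop_pataka("need >= 2 participants in each of PD and control",
                "pataka_input_error")
  n <- nrow(table)
  mtry <- if (is.null(spec$mtry))
    max(1L, floor(sqrt(length(spec$features)))) else spec$mtry
  with_seed(spec$seed, {
    per_repeat <- matrix(NA_real_, spec$n_repeats, 3,
                         dimnames = list(NULL, c("accuracy", "sensitivity",
                                                 "specificity")))
    conf <- matrix(0, 2, 2, dimnames = list(true = c("PD", "control"),
                                            pred = c("PD", "control")))
    for (r in seq_len(spec$n_repeats)) {
      pred <- factor(rep(NA_character_, n), levels = levels(y))
      for (i in seq_len(n)) {
        folds <- impute_fold(table[-i, , drop = FALSE],
                             table[i, , drop = FALSE], spec$features)
        fit <- randomForest::randomForest(
          x = folds$train[spec$features], y = y[-i],
          ntree = spec$ntree, mtry = mtry)
        pred[i] <- stats::predict(fit, folds$test[spec$features])
      }
      per_repeat[r, ] <- confusion_metrics(y, pred)
      conf <- conf + base::table(true = y, pred = pred)
    }
    structure(list(
      model_id = spec$model_id, features = spec$features,
      metrics = colMeans(per_repeat),
      metrics_sd = apply(per_repeat, 2, stats::sd),
      per_repeat = as.data.frame(per_repeat),
      confusion = conf / spec$n_repeats,
      n_pd = sum(y == "PD"), n_ctrl = sum(y == "control"),
      n_repeats = spec$n_repeats),
      class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Random-forest screener, model %s (%d PD / %d control)\n",
              x$model_id, x$n_pd, x$n_ctrl))
  cat("features:", paste(x$features, collapse = " + "), "\n")
  cat(sprintf(
    "%d-repeat LOO: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$n_repeats, x$metrics["accuracy"], x$metrics["sensitivity"],
    x$metrics["specificity"]))
  invisible(x)
}

#' Evaluate the full model suite
#'
#' @param table A `cohort_table`.
#' @param specs List of [model_spec()] objects (default: models 1-4).
#' @param ... Passed to [model_spec()] when building the default specs
#'   (e.g. `n_repeats`, `seed`).
#' @return Object of class `model_suite` (list of `classifier_report`s);
#'   `as.data.frame()` renders the report table (model, parameters,
#'   accuracy, sensitivity, specificity).
#' @export
run_model_suite <- function(table, specs = NULL, ...) {
  if (is.null(specs)) specs <- lapply(1:4, model_spec, ...)
  reports <- lapply(specs, function(s) loo_evaluate(table, s))
  structure(reports, class = "model_suite")
}

#' @export
as.data.frame.model_suite <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    model = r$model_id,
    parameters = paste(r$features, collapse = " + "),
    accuracy = round(unname(r$metrics["accuracy"]), 1),
    sensitivity = round(unname(r$metrics["sensitivity"]), 1),
    specificity = round(unname(r$metrics["specificity"]), 1),
    stringsAsFactors = FALSE)))
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Random-forest screener performance (repeated leave-one-out)\n\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
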