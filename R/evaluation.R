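#' Confusion-matrix metrics
#'
#' Sensitivity = 100 TP/(TP+FN) (inhibitors correctly recognized),
#' specificity = 100 TN/(TN+FP), and the rate of correct classification
#' CCR = 100 (TP+TN)/n. CCR is always the prevalence-weighted mean of
#' sensitivity and specificity. A metric whose denominator is empty is
#' reported as NA with a warning.
#'
#' @param y_true,y_pred Binary vectors of equal length (inhibitor = 1).
#' @return Object of class \code{"metrics_report"}: the three percentages
#'   plus TP/FP/TN/FN and class counts.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as_binary(y_true); y_pred <- as_binary(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == 1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  sens <- if (tp + fn == 0L) { warning("no positives: sensitivity undefined"); NA_real_ }
          else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0L) { warning("no negatives: specificity undefined"); NA_real_ }
          else 100 * tn / (tn + fp)
  structure(list(
    correct_classification = 100 * (tp + tn) / length(y_true),
    sensitivity = sens, specificity = spec,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_positive = tp + fn, n_negative = tn + fp),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(m, ci) {
    if (is.null(ci)) sprintf("%.1f", m) else sprintf("%.1f ± %.1f", m, ci)
  }
  cat(sprintf("correct classification: %s%%\nsensitivity:            %s%%\nspecificity:            %s%%\n",
              fmt(x$correct_classification, x$ci95$correct_classification),
              fmt(x$sensitivity, x$ci95$sensitivity),
              fmt(x$specificity, x$ci95$specificity)))
  invisible(x)
}

#' Cross-validation settings
#'
#' @param n_folds Folds per repeat (default 10: the dataset is divided into
#'   ten equal portions, any remainder spread one per fold).
#' @param n_repeats Number of repeated random divisions (default 100).
#' @param seed Integer seed; all fold randomness flows from it.
#' @param mode \code{"pooled"} (default): within a repeat, held-out
#'   predictions from the 10 folds are pooled before computing metrics.
#'   \code{"fold_averaged"}: metrics per fold, averaged over the folds.
#' @param stratified Stratify fold assignment by class (default FALSE:
#'   plain random division).
#' @return List of class \code{"cv_config"}.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 100L, seed = 1L,
                      mode = c("pooled", "fold_averaged"),
                      stratified = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), mode = mode,
                 stratified = stratified),
            class = "cv_config")
}

#' Repeated k-fold cross-validation
#'
#' Within each repeat the data are randomly divided into \code{n_folds}
#' portions; each portion is held out once while the model is fit on the
#' rest. Metrics are computed per repeat (pooled over held-out predictions
#' by default) and then averaged over repeats with t-based 95% confidence
#' intervals (df = repeats - 1). If a training fold loses an entire class
#' the repeat's folds are resampled once, then an error is raised.
#'
#' @param X Feature matrix (or occupancy matrix counts).
#' @param y Binary labels.
#' @param fit Function \code{(X_train, y_train) -> model}; the model must
#'   have a \code{predict} method returning a data.frame with a
#'   \code{class} column (as the package's models do).
#' @param config A [cv_config()].
#' @return \code{"metrics_report"} with the across-repeat means, a
#'   \code{ci95} list of half-widths, the \code{per_repeat} data.frame, and
#'   a \code{provenance} record.
#' @export
repeated_cv <- function(X, y, fit, config = cv_config()) {
  if (inherits(X, "occupancy_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$counts
  }
  X <- as.matrix(X)
  y <- as_binary(y)
  n <- nrow(X)
  stopifnot(n >= config$n_folds, length(y) == n)

  per_repeat <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(config$n_repeats), function(r) {
      folds <- make_folds(y, config$n_folds, config$stratified)
      if (!folds_trainable(folds, y, config$n_folds)) {
        folds <- make_folds(y, config$n_folds, config$stratified)
        if (!folds_trainable(folds, y, config$n_folds)) {
          stop("a training fold lost an entire class even after resampling")
        }
      }
      fold_metrics <- lapply(seq_len(config$n_folds), function(k) {
        hold <- folds == k
        model <- fit(X[!hold, , drop = FALSE], y[!hold])
        pred <- stats::predict(model, X[hold, , drop = FALSE])
        list(y_true = y[hold], y_pred = pred$class)
      })
      if (config$mode == "pooled") {
        m <- confusion_metrics(unlist(lapply(fold_metrics, `[[`, "y_true")),
                               unlist(lapply(fold_metrics, `[[`, "y_pred")))
        data.frame(repeat_id = r, ccr = m$correct_classification,
                   sensitivity = m$sensitivity, specificity = m$specificity)
      } else {
        ms <- lapply(fold_metrics, function(f) {
          suppressWarnings(confusion_metrics(f$y_true, f$y_pred))
        })
        data.frame(
          repeat_id = r,
          ccr = mean(vapply(ms, `[[`, numeric(1), "correct_classification")),
          sensitivity = mean(vapply(ms, `[[`, numeric(1), "sensitivity"),
                             na.rm = TRUE),
          specificity = mean(vapply(ms, `[[`, numeric(1), "specificity"),
                             na.rm = TRUE))
      }
    }))
  })

  ci <- function(v) {
    if (config$n_repeats < 2L) return(0)
    stats::qt(0.975, config$n_repeats - 1L) *
      stats::sd(v) / sqrt(config$n_repeats)
  }
  out <- structure(list(
    correct_classification = mean(per_repeat$ccr),
    sensitivity = mean(per_repeat$sensitivity),
    specificity = mean(per_repeat$specificity),
    n_positive = sum(y == 1L), n_negative = sum(y == 0L),
    ci95 = list(correct_classification = ci(per_repeat$ccr),
                sensitivity = ci(per_repeat$sensitivity),
                specificity = ci(per_repeat$specificity)),
    per_repeat = per_repeat,
    provenance = list(n_folds = config$n_folds, n_repeats = config$n_repeats,
                      seed = config$seed, mode = config$mode,
                      stratified = config$stratified, n = n)),
    class = "metrics_report")
  out
}

make_folds <- function(y, k, stratified) {
  n <- length(y)
  if (!stratified) {
    sample(rep_len(seq_len(k), n))
  } else {
    folds <- integer(n)
    for (g in c(0L, 1L)) {
      idx <- which(y == g)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  }
}

folds_trainable <- function(folds, y, k) {
  all(vapply(seq_len(k), function(kk) {
    length(unique(y[folds != kk])) == 2L
  }, logical(1)))
}

#' External validation of a fitted model
#'
#' Applies an already-fitted model to a held-out external set; no refitting.
#'
#' @param model A fitted \code{"stepwise_lda"} or \code{"decision_forest"}.
#' @param X_ev Feature matrix of the external set (must cover the model's
#'   variables; an error lists any missing columns).
#' @param y_ev External labels.
#' @return A \code{"metrics_report"}.
#' @export
external_validate <- function(model, X_ev, y_ev) {
  if (inherits(X_ev, "occupancy_matrix")) {
    if (is.null(y_ev)) y_ev <- X_ev$labels
    X_ev <- X_ev$counts
  }
  X_ev <- as.matrix(X_ev)
  if (nrow(X_ev) == 0L) stop("external validation set is empty")
  pred <- stats::predict(model, X_ev)
  confusion_metrics(y_ev, pred$class)
}

#' Fraction of inhibitors in a label vector
#' @param y Binary labels (inhibitor = 1).
#' @return Percentage (0-100).
#' @export
inhibitor_fraction <- function(y) {
  y <- as_binary(y)
  if (!length(y)) stop("empty label vector")
  100 * mean(y == 1L)
}

#' Write a metrics report as CSV (+ JSON provenance sidecar)
#' @param report A \code{"metrics_report"}.
#' @param path CSV path; provenance goes to \code{<path>.json}.
#' @param provenance Optional extra provenance fields.
#' @return The path, invisibly.
#' @export
write_metrics_report <- function(report, path, provenance = list()) {
  df <- data.frame(
    metric = c("correct_classification", "sensitivity", "specificity"),
    value = c(report$correct_classification, report$sensitivity,
              report$specificity))
  if (!is.null(report$ci95)) {
    df$ci95_halfwidth <- c(report$ci95$correct_classification,
                           report$ci95$sensitivity, report$ci95$specificity)
  }
  utils::write.csv(format(df, digits = 10), path, row.names = FALSE)
  prov <- c(report$provenance, provenance,
            list(package_version = as.character(utils::packageVersion("sdarforest"))))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
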