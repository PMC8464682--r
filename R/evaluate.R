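#' Configuration of the cross-validated evaluation
#'
#' @param n_folds Outer stratified folds (shrinks with a warning if the
#'   minority class is smaller).
#' @param trees Trees of the final per-fold random forest.
#' @param mtry Candidate features per split (`NULL` = floor(sqrt(p))).
#' @param select_inside_folds Run [best_first_select()] on each training
#'   fold (the bias-free protocol); `FALSE` fits on all features.
#' @param threshold Probability cut for the pooled confusion matrix.
#' @param select A [select_config()] for the in-fold selection.
#' @return List of class `eval_config`.
#' @export
eval_config <- function(n_folds = 10, trees = 100, mtry = NULL,
                        select_inside_folds = TRUE, threshold = 0.5,
                        select = select_config()) {
  structure(list(n_folds = n_folds, trees = trees, mtry = mtry,
                 select_inside_folds = select_inside_folds,
                 threshold = threshold, select = select),
            class = "eval_config")
}

confusion_metrics <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) 0 else num / den
  flags <- character(0)
  if (tp + fn == 0) flags <- c(flags, "sensitivity")
  if (tn + fp == 0) flags <- c(flags, "specificity")
  if (tp + fp == 0) flags <- c(flags, "ppv")
  if (tn + fn == 0) flags <- c(flags, "npv")
  list(metrics = c(accuracy = (tp + tn) / (tp + fp + tn + fn),
                   sensitivity = ratio(tp, tp + fn),
                   specificity = ratio(tn, tn + fp),
                   ppv = ratio(tp, tp + fp),
                   npv = ratio(tn, tn + fn)),
       degenerate = flags)
}

#' Cross-validated evaluation of one dichotomous label
#'
#' Stratified k-fold cross-validation with the wrapper selection nested
#' inside each training fold: per fold, [best_first_select()] picks a
#' subset on the training rows only, a random forest is fit on it, and
#' class probabilities are predicted for the held-out rows. Held-out
#' predictions are pooled into a single ROC (one AUC per experiment) and a
#' single confusion matrix at `threshold`. Ratios with an empty denominator
#' are reported as 0 and flagged, so an all-negative classifier on an
#' imbalanced label yields sensitivity 0 / PPV 0 rather than NaN.
#'
#' @param x Data frame of features (rows = lesions).
#' @param y Binary label vector.
#' @param cfg An [eval_config()].
#' @param seed Master seed (folds, selection, forests).
#' @param folds Optional precomputed fold assignment (used by
#'   [compare_configurations()] to share folds across arms).
#' @param label Label name carried into the report.
#' @return Object of class `edema_eval`: metrics, pooled confusion matrix,
#'   per-fold selected features, pooled predictions, fold assignment.
#' @export
crossval_evaluate <- function(x, y, cfg = eval_config(), seed = 1L,
                              folds = NULL, label = "label") {
  x <- as.data.frame(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("single-class cohort: cannot evaluate")
  if (is.null(folds)) folds <- stratified_folds(y, cfg$n_folds, seed)
  k <- attr(folds, "k")
  seeds <- derive_seeds(seed, k)

  prob <- numeric(length(y))
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (cfg$select_inside_folds) {
      sel <- best_first_select(x[tr, , drop = FALSE], y[tr],
                               cfg = cfg$select, seed = seeds[f])
      cols <- sel$features
    } else {
      cols <- names(x)
    }
    selected[[f]] <- cols
    fit <- rf_fit(x[tr, cols, drop = FALSE], y[tr], cfg$trees,
                  mtry = cfg$mtry, seed = seeds[f])
    prob[!tr] <- rf_predict(fit, x[!tr, cols, drop = FALSE])
  }

  pred <- as.integer(prob >= cfg$threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  cm <- confusion_metrics(tp, fp, tn, fn)
  structure(list(
    label = label,
    configuration = if (cfg$select_inside_folds) "selected" else "all-features",
    n = length(y),
    n_folds = k,
    seed = as.integer(seed),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    auc = auc_mann_whitney(prob, y),
    metrics = cm$metrics,
    degenerate = cm$degenerate,
    selected = selected,
    predictions = tibble::tibble(row = seq_along(y), fold = as.integer(folds),
                                 prob = prob, truth = y),
    folds = folds
  ), class = "edema_eval")
}

#' @export
print.edema_eval <- function(x, ...) {
  cat(sprintf("<edema_eval '%s' (%s): n=%d, %d folds>\n",
              x$label, x$configuration, x$n, x$n_folds))
  cat(sprintf("  AUC %.3f | ACC %.3f | Se %.3f | Sp %.3f | PPV %.3f | NPV %.3f\n",
              x$auc, x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"], x$metrics["ppv"], x$metrics["npv"]))
  if (length(x$degenerate) > 0) {
    cat("  zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report into one row per metric
#' @param x An `edema_eval`.
#' @param ... Unused.
#' @method tidy edema_eval
#' @export
tidy.edema_eval <- function(x, ...) {
  tibble::tibble(label = x$label, configuration = x$configuration,
                 metric = c("auc", names(x$metrics)),
                 value = unname(c(x$auc, x$metrics)))
}

#' One-row summary of an evaluation report
#' @param x An `edema_eval`.
#' @param ... Unused.
#' @method glance edema_eval
#' @export
glance.edema_eval <- function(x, ...) {
  tibble::tibble(label = x$label, configuration = x$configuration,
                 n = x$n, n_folds = x$n_folds, auc = x$auc,
                 accuracy = unname(x$metrics["accuracy"]),
                 sensitivity = unname(x$metrics["sensitivity"]),
                 specificity = unname(x$metrics["specificity"]),
                 ppv = unname(x$metrics["ppv"]),
                 npv = unname(x$metrics["npv"]),
                 tp = unname(x$confusion["tp"]), fp = unname(x$confusion["fp"]),
                 tn = unname(x$confusion["tn"]), fn = unname(x$confusion["fn"]))
}

roc_points <- function(prob, truth) {
  ord <- order(-prob)
  tibble::tibble(
    fpr = c(0, cumsum(truth[ord] == 0) / sum(truth == 0)),
    tpr = c(0, cumsum(truth[ord] == 1) / sum(truth == 1))
  )
}

#' ROC curve of the pooled held-out predictions
#' @param object An `edema_eval`.
#' @param ... Unused.
#' @method autoplot edema_eval
#' @export
autoplot.edema_eval <- function(object, ...) {
  pts <- roc_points(object$predictions$prob, object$predictions$truth)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s (%s): pooled CV ROC, AUC = %.3f",
                                  object$label, object$configuration,
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
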