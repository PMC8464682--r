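#' Configuration of the best-first wrapper selection
#'
#' @param trees Trees per random-forest merit evaluation.
#' @param internal_folds Stratified folds of the internal cross-validation
#'   that scores a candidate subset on the training data.
#' @param patience Consecutive node expansions without a merit improvement
#'   greater than `merit_eps` before the search stops.
#' @param merit_eps Minimum merit improvement that counts as progress.
#' @param max_size Optional cap on the selected subset size.
#' @param screen_top Before the search, keep only the `screen_top` features
#'   with the largest univariate |AUC - 0.5| on the training data
#'   (`Inf` = no screening). Screening happens inside the training fold,
#'   so it cannot leak test information.
#' @return List of class `select_config`.
#' @export
select_config <- function(trees = 50, internal_folds = 5, patience = 5,
                          merit_eps = 1e-4, max_size = Inf, screen_top = Inf) {
  structure(list(trees = trees, internal_folds = internal_folds,
                 patience = patience, merit_eps = merit_eps,
                 max_size = max_size, screen_top = screen_top),
            class = "select_config")
}

rf_fit <- function(x, y, trees, mtry = NULL, seed = 1L) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  ranger::ranger(.y ~ ., data = df, num.trees = trees,
                 mtry = if (is.null(mtry)) max(1, floor(sqrt(ncol(x)))) else mtry,
                 probability = TRUE, seed = as.integer(seed), num.threads = 1)
}

rf_predict <- function(fit, x) {
  p <- stats::predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  p[, "1"]
}

# mean AUC of the RF evaluator over an internal stratified CV on (x, y),
# restricted to the candidate subset
subset_merit <- function(x, y, subset, folds, trees, seed) {
  aucs <- vapply(seq_len(attr(folds, "k")), function(f) {
    tr <- folds != f
    fit <- rf_fit(x[tr, subset, drop = FALSE], y[tr], trees, seed = seed + f)
    auc_mann_whitney(rf_predict(fit, x[!tr, subset, drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Best-first wrapper feature selection with a random-forest evaluator
#'
#' Forward best-first search over feature subsets. Each candidate subset is
#' scored ("merit") by the mean AUC of a random forest under internal
#' stratified cross-validation on the supplied data; the open list is
#' ordered by merit and the best node is expanded by adding one unused
#' feature at a time. The search stops after `patience` consecutive
#' expansions that fail to improve the best merit by more than `merit_eps`.
#' Deterministic under `seed` and the canonical feature order; merit ties
#' resolve to the earlier feature.
#'
#' @param x Data frame / matrix of candidate features (training rows only —
#'   when used inside cross-validation the caller passes the training fold).
#' @param y Binary label vector aligned with the rows of `x`.
#' @param cfg A [select_config()].
#' @param seed Seed for internal folds and forest fits.
#' @return List: `features` (selected column names, at least one), `merit`
#'   (internal-CV AUC of the selected subset), `n_evaluated` (number of
#'   subsets scored), `candidates` (column names surviving the screen).
#' @export
best_first_select <- function(x, y, cfg = select_config(), seed = 1L) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("single-class input: nothing to select for")
  stopifnot(nrow(x) == length(y), ncol(x) >= 1)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  cand <- seq_len(ncol(x))
  if (is.finite(cfg$screen_top) && ncol(x) > cfg$screen_top) {
    u <- vapply(cand, function(j) {
      if (stats::sd(x[[j]]) == 0) return(0)
      abs(auc_mann_whitney(x[[j]], y) - 0.5)
    }, numeric(1))
    cand <- sort(order(-u)[seq_len(cfg$screen_top)])  # ties: earlier feature
  }

  folds <- suppressWarnings(stratified_folds(y, cfg$internal_folds, seed))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  merit_of <- function(subset) {
    key <- paste(subset, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- subset_merit(x, y, subset, folds, cfg$trees, seed)
    n_eval <<- n_eval + 1L
    cache[[key]] <- m
    m
  }

  open <- list(list(subset = integer(0), merit = -Inf))
  best <- list(subset = integer(0), merit = -Inf)
  stale <- 0L
  while (length(open) > 0 && stale < cfg$patience) {
    pick <- which.max(vapply(open, `[[`, numeric(1), "merit"))
    node <- open[[pick]]
    open <- open[-pick]
    if (length(node$subset) >= cfg$max_size) next
    improved <- FALSE
    for (j in setdiff(cand, node$subset)) {
      subset <- c(node$subset, j)
      key <- paste(subset, collapse = ",")
      already <- !is.null(cache[[key]])
      m <- merit_of(subset)
      if (!already) open <- c(open, list(list(subset = subset, merit = m)))
      if (m > best$merit + cfg$merit_eps) {
        best <- list(subset = subset, merit = m)
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  if (length(best$subset) == 0) {
    # no subset cleared the improvement threshold over -Inf start: take the
    # single best-scoring feature so downstream models always have input
    singles <- vapply(cand, function(j) merit_of(j), numeric(1))
    best <- list(subset = cand[which.max(singles)], merit = max(singles))
  }
  list(features = names(x)[best$subset], merit = best$merit,
       n_evaluated = n_eval, candidates = names(x)[cand])
}
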