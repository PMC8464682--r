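#' Derive reproducible child seeds from a master seed
#'
#' All stochastic stages (cohort generation, fold assignment, forest fits)
#' draw their own seed from the master seed through this helper, so that a
#' single integer reproduces an entire pipeline run.
#'
#' @param seed Master seed (integer).
#' @param n Number of child seeds to derive.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds preserving class balance: indices are
#' shuffled within each class and dealt round-robin. If the minority class
#' has fewer members than `k`, the fold count shrinks to that size with a
#' warning so every fold sees both classes.
#'
#' @param y Binary vector (0/1 or logical).
#' @param k Number of folds requested.
#' @param seed Seed for the within-class shuffle.
#' @return Integer vector of fold ids (1..k') aligned with `y`, with the
#'   realized fold count in attribute `"k"`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  n_min <- min(table(factor(y, levels = c(0, 1))))
  if (n_min < 2) stop("need at least 2 samples in each class")
  k_eff <- as.integer(min(k, n_min))
  if (k_eff < k) {
    warning(sprintf("minority class has %d members; shrinking to %d folds",
                    n_min, k_eff))
  }
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
  })
  attr(folds, "k") <- k_eff
  folds
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes AUC as the normalized Mann-Whitney U statistic on the score
#' ranks, so ties contribute 1/2. Equivalent to the probability that a
#' randomly chosen positive scores above a randomly chosen negative.
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Binary vector aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
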