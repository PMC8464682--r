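#' Paired comparison: semantic-only vs semantic + edema radiomics
#'
#' For each label, runs [crossval_evaluate()] twice on identical folds and
#' seeds: once on the 11 semantic columns only, once on the full 253-column
#' bank. Sharing folds makes the per-label delta a paired contrast, so the
#' question answered is exactly "does adding edema texture to the clinical
#' picture move the cross-validated AUC, and in which direction".
#'
#' @param features Tibble with the canonical 253 feature columns (an
#'   optional `lesion_id` column is ignored for modeling).
#' @param labels Tibble of `label_*` columns (from [dichotomize()] or
#'   [generate_cohort()]), rows aligned with `features`.
#' @param cfg An [eval_config()].
#' @param seed Master seed.
#' @return Object of class `edema_comparison`: named list of per-label
#'   `semantic` / `combined` reports plus the delta table. Labels with a
#'   single observed class are skipped with a warning.
#' @export
compare_configurations <- function(features, labels, cfg = eval_config(),
                                   seed = 1L) {
  feat <- dplyr::select(features, -dplyr::any_of("lesion_id"))
  stopifnot(all(feature_names() %in% names(feat)))
  sem_cols <- feature_names()[1:11]
  label_cols <- grep("^label_", names(labels), value = TRUE)
  if (length(label_cols) == 0) stop("no label_* columns found")
  seeds <- derive_seeds(seed, length(label_cols))

  results <- list()
  for (i in seq_along(label_cols)) {
    lc <- label_cols[i]
    nm <- sub("^label_", "", lc)
    y <- labels[[lc]]
    if (length(unique(y)) < 2) {
      warning(sprintf("label '%s' has a single class; skipped", nm))
      next
    }
    folds <- stratified_folds(y, cfg$n_folds, seeds[i])
    sem <- crossval_evaluate(feat[sem_cols], y, cfg, seed = seeds[i],
                             folds = folds, label = nm)
    sem$configuration <- "semantic"
    full <- crossval_evaluate(feat[feature_names()], y, cfg, seed = seeds[i],
                              folds = folds, label = nm)
    full$configuration <- "combined"
    results[[nm]] <- list(semantic = sem, combined = full)
  }
  if (length(results) == 0) stop("no evaluable label")
  structure(list(results = results, seed = as.integer(seed)),
            class = "edema_comparison")
}

#' Long tidy table of a paired comparison
#'
#' One row per label x arm x metric (6 metrics: AUC, accuracy,
#' sensitivity, specificity, PPV, NPV).
#' @param x An `edema_comparison`.
#' @param ... Unused.
#' @method tidy edema_comparison
#' @export
tidy.edema_comparison <- function(x, ...) {
  purrr::map_dfr(x$results, function(pair) {
    dplyr::bind_rows(tidy(pair$semantic), tidy(pair$combined))
  })
}

#' Per-label metric deltas (combined minus semantic-only)
#'
#' @param x An `edema_comparison`.
#' @param ... Unused.
#' @return Tibble: label, metric, semantic, combined, delta.
#' @method glance edema_comparison
#' @export
glance.edema_comparison <- function(x, ...) {
  tidy(x) |>
    tidyr::pivot_wider(names_from = "configuration", values_from = "value") |>
    dplyr::mutate(delta = .data$combined - .data$semantic)
}

#' @export
print.edema_comparison <- function(x, ...) {
  cat(sprintf("<edema_comparison: %d labels, paired folds, seed %d>\n",
              length(x$results), x$seed))
  d <- glance(x) |> dplyr::filter(.data$metric == "auc")
  for (r in seq_len(nrow(d))) {
    cat(sprintf("  %-10s AUC %.3f -> %.3f (delta %+.3f)\n",
                d$label[r], d$semantic[r], d$combined[r], d$delta[r]))
  }
  invisible(x)
}

#' Dot plot of semantic-only vs combined AUC per label
#' @param object An `edema_comparison`.
#' @param ... Unused.
#' @method autoplot edema_comparison
#' @export
autoplot.edema_comparison <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$metric == "auc")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$label,
                                  colour = .data$configuration)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(group = .data$label), colour = "grey40") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Cross-validated AUC", y = NULL, colour = NULL,
                  title = "Semantic-only vs semantic + edema radiomics") +
    ggplot2::theme_minimal()
}
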