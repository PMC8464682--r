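semantic_fields <- c("age", "menopause", "family_history", "hormone_therapy",
                     "location", "stadiation", "margins", "dimensions",
                     "morphology", "kinetic_curve", "edema_type")

fo_stat_names <- c("mean", "sd", "skewness", "kurtosis", "energy", "entropy",
                   "max", "max_position", "max_energy", "range",
                   "n_rel_max", "rel_max_energy")

#' Canonical names of the 253 per-lesion features
#'
#' The fixed feature bank: 11 semantic descriptors (`sem_*`), 12 first-order
#' histogram statistics (`fo_*`), 48 LBP-TOP features (`lbp_<variant>_<stat>`,
#' variant-major) and 182 co-occurrence features (`glcm_<dir>_<stat>`,
#' direction-major over the 26 directed displacements). The order is frozen;
#' every feature table this package emits uses exactly these names in
#' exactly this order.
#'
#' @return Character vector of length 253.
#' @export
feature_names <- function() {
  c(paste0("sem_", semantic_fields),
    paste0("fo_", fo_stat_names),
    as.vector(t(outer(c("basic", "ri", "u2", "riu2"), fo_stat_names,
                      function(v, s) paste0("lbp_", v, "_", s)))),
    as.vector(t(outer(sprintf("%02d", 1:26), glcm_stat_names,
                      function(d, s) paste0("glcm_", d, "_", s)))))
}

#' Feature manifest: name, block and index of every feature
#'
#' @return Tibble with columns `index`, `name`, `block`
#'   (semantic / first_order / lbp_top / glcm).
#' @export
feature_manifest <- function() {
  nm <- feature_names()
  tibble::tibble(
    index = seq_along(nm),
    name = nm,
    block = c(rep("semantic", 11), rep("first_order", 12),
              rep("lbp_top", 48), rep("glcm", 182))
  )
}

#' Names of the radiomic (non-semantic) features
#' @return Character vector of length 242.
#' @export
radiomic_feature_names <- function() {
  feature_names()[-(1:11)]
}

encode_semantic <- function(record) {
  record <- as.list(record)
  vals <- vapply(semantic_fields, function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      stop(sprintf("missing semantic value: %s", f))
    }
    as.numeric(v)
  }, numeric(1))
  stats::setNames(vals, paste0("sem_", semantic_fields))
}

#' Extract the full 253-feature vector for one lesion
#'
#' Concatenates the numerically encoded semantic descriptors with the three
#' radiomic blocks computed on the (hull-refined) edema ROI. The radiomic
#' sub-vector depends only on `volume` and `mask`; the semantic sub-vector
#' only on `record`.
#'
#' @param volume 3D integer array (T2 gray levels).
#' @param mask Logical 3D array: the edema ROI, after any hull refinement.
#' @param record Named list / one-row data frame holding the 11 semantic
#'   fields (age, menopause, family_history, hormone_therapy, location,
#'   stadiation, margins, dimensions, morphology, kinetic_curve,
#'   edema_type), numerically encoded.
#' @param w Peak-window half-width for the histogram statistics.
#' @return Named numeric vector of length 253 in canonical order.
#' @export
extract_lesion_features <- function(volume, mask, record, w = 5) {
  check_volume_mask(volume, mask)
  if (!any(mask)) stop("empty mask: refine/segment before extraction")
  out <- c(encode_semantic(record),
           first_order_features(intensity_histogram(volume, mask), w = w),
           lbp_top_features(volume, mask, w = w),
           glcm_features(volume, mask))
  stopifnot(identical(names(out), feature_names()))
  if (!all(is.finite(out))) {
    stop("non-finite feature value produced: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Extract features for a whole cohort
#'
#' Maps [extract_lesion_features()] over a cohort tibble (as produced by
#' [generate_cohort()] or [read_cohort()]), optionally refining each mask
#' with [convex_hull_refine()] first.
#'
#' @param cohort Tibble with columns `lesion_id`, `volume` (list of 3D
#'   arrays), `mask` (list of logical arrays) and the 11 semantic columns.
#' @param refine_hull Apply the 3D convex-hull refinement to each mask
#'   before extraction (the pipeline default).
#' @param w Peak-window half-width for the histogram statistics.
#' @return Tibble: `lesion_id` plus the 253 feature columns.
#' @export
extract_features <- function(cohort, refine_hull = TRUE, w = 5) {
  stopifnot(all(c("lesion_id", "volume", "mask") %in% names(cohort)))
  rows <- purrr::pmap(
    list(cohort$volume, cohort$mask, seq_len(nrow(cohort))),
    function(vol, msk, i) {
      if (refine_hull) msk <- convex_hull_refine(msk)
      fv <- extract_lesion_features(vol, msk, cohort[i, , drop = FALSE], w = w)
      tibble::as_tibble(as.list(fv))
    })
  dplyr::bind_cols(tibble::tibble(lesion_id = cohort$lesion_id),
                   dplyr::bind_rows(rows))
}
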