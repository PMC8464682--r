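#' Dichotomize raw histology fields into the five binary labels
#'
#' Maps each lesion's raw pathology record to the five 0/1 prediction
#' targets: histology (IDC = 0 vs ILC = 1), grading (G1+G2 = 0 vs G3 = 1 —
#' the minority class grouped against the rest), ER and PgR status
#' (percentage at or above threshold = 1) and Ki-67 (at or above threshold
#' = 1). Receptor thresholds default to 1% and Ki-67 to 14%; both are
#' configurable because reporting conventions differ between labs (10% for
#' receptors and 20% for Ki-67 are common alternatives).
#'
#' @param records Data frame with columns `histological_type`
#'   ("IDC"/"ILC"), `grade` (1-3), `er_pct`, `pgr_pct`, `ki67_pct`
#'   (percentages in 0..100), plus an optional `lesion_id`.
#' @param thresholds Named list: `er`, `pgr`, `ki67` cut points (>=
#'   threshold is positive).
#' @return Tibble with `lesion_id` (if present) and integer columns
#'   `label_histology`, `label_grading`, `label_er`, `label_pgr`,
#'   `label_ki67`.
#' @export
#' @examples
#' rec <- tibble::tibble(histological_type = "IDC", grade = 3,
#'                       er_pct = 1, pgr_pct = 0.9, ki67_pct = 14)
#' dichotomize(rec)
dichotomize <- function(records, thresholds = list(er = 1, pgr = 1, ki67 = 14)) {
  needed <- c("histological_type", "grade", "er_pct", "pgr_pct", "ki67_pct")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("missing raw histology field(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(records$histological_type %in% c("IDC", "ILC")),
            all(records$grade %in% 1:3),
            all(records$er_pct >= 0 & records$er_pct <= 100),
            all(records$pgr_pct >= 0 & records$pgr_pct <= 100),
            all(records$ki67_pct >= 0 & records$ki67_pct <= 100))
  out <- tibble::tibble(
    label_histology = as.integer(records$histological_type == "ILC"),
    label_grading = as.integer(records$grade == 3),
    label_er = as.integer(records$er_pct >= thresholds$er),
    label_pgr = as.integer(records$pgr_pct >= thresholds$pgr),
    label_ki67 = as.integer(records$ki67_pct >= thresholds$ki67)
  )
  if ("lesion_id" %in% names(records)) {
    out <- dplyr::bind_cols(tibble::tibble(lesion_id = records$lesion_id), out)
  }
  out
}
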