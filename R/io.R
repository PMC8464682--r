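cohort_scalar_cols <- function(cohort) {
  dplyr::select(cohort, -dplyr::any_of(c("volume", "mask")))
}

#' Write a cohort to disk
#'
#' Per lesion, the volume and mask go to NIfTI (`<id>_vol.nii.gz`,
#' `<id>_mask.nii.gz`) with the voxel spacing in the header; the tabular
#' part (semantic fields, raw histology, labels, truth columns) goes to
#' `cohort.csv` and the generating [cohort_spec()] (when attached) to
#' `cohort_spec.json`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$volume)) {
    for (i in seq_len(nrow(cohort))) {
      id <- cohort$lesion_id[i]
      vol <- cohort$volume[[i]]
      sp <- attr(vol, "spacing") %||% c(1, 1, 1)
      img <- RNifti::asNifti(array(as.integer(vol), dim(vol)))
      RNifti::pixdim(img) <- sp
      RNifti::writeNifti(img, file.path(dir, paste0(id, "_vol.nii.gz")))
      msk <- cohort$mask[[i]]
      mimg <- RNifti::asNifti(array(as.integer(msk), dim(msk)))
      RNifti::pixdim(mimg) <- sp
      RNifti::writeNifti(mimg, file.path(dir, paste0(id, "_mask.nii.gz")))
    }
  }
  readr::write_csv(cohort_scalar_cols(cohort), file.path(dir, "cohort.csv"))
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]: reads `cohort.csv` and, when present,
#' the per-lesion NIfTI volume/mask pairs. Refuses a mask whose grid does
#' not match its volume.
#'
#' @param dir Cohort directory.
#' @return Cohort tibble (with `volume`/`mask` list-columns when image
#'   files exist).
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", dir)
  cohort <- readr::read_csv(csv, show_col_types = FALSE)
  vol_files <- file.path(dir, paste0(cohort$lesion_id, "_vol.nii.gz"))
  if (all(file.exists(vol_files))) {
    cohort$volume <- lapply(seq_len(nrow(cohort)), function(i) {
      img <- RNifti::readNifti(vol_files[i])
      voxel_volume(array(as.integer(img), dim(img)),
                   RNifti::pixdim(img)[1:3])
    })
    cohort$mask <- lapply(seq_len(nrow(cohort)), function(i) {
      img <- RNifti::readNifti(file.path(dir, paste0(cohort$lesion_id[i], "_mask.nii.gz")))
      m <- roi_mask(array(as.integer(img) != 0, dim(img)))
      check_volume_mask(cohort$volume[[i]], m)
      m
    })
  }
  cohort
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

provenance <- function(seed, config = NULL) {
  list(package = "edemaradiomics",
       version = as.character(utils::packageVersion("edemaradiomics")),
       seed = seed,
       config = config,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Simulate a cohort to disk
#'
#' @param out_dir Output directory.
#' @param spec A [cohort_spec()].
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(out_dir, spec = cohort_spec()) {
  cohort <- generate_cohort(spec)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

#' Extract features for a cohort on disk
#'
#' Hull-refines each mask (unless `refine_hull = FALSE`), extracts the 253
#' features per lesion and writes `features.csv` plus the frozen feature
#' manifest `feature_manifest.json`.
#'
#' @param cohort_dir Directory written by [run_simulate()] /
#'   [write_cohort()].
#' @param out_dir Output directory.
#' @param refine_hull Apply [convex_hull_refine()] before extraction.
#' @return The feature tibble, invisibly.
#' @export
run_extract <- function(cohort_dir, out_dir, refine_hull = TRUE) {
  cohort <- read_cohort(cohort_dir)
  if (is.null(cohort$volume)) stop("cohort at ", cohort_dir, " has no image files")
  feats <- extract_features(cohort, refine_hull = refine_hull)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(feats, file.path(out_dir, "features.csv"))
  jsonlite::write_json(feature_manifest(),
                       file.path(out_dir, "feature_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(feats)
}

#' Evaluate the paired semantic vs semantic+radiomics models on disk
#'
#' Reads a features table and a labels table, runs
#' [compare_configurations()] for every `label_*` column, and writes
#' per-label report JSONs, a delta CSV in the with/without-radiomics
#' layout, per-fold selected-feature lists and a provenance block.
#'
#' @param features_csv Path to the features CSV (from [run_extract()]).
#' @param labels_csv Path to a CSV holding `lesion_id` and `label_*`
#'   columns (a cohort.csv works).
#' @param out_dir Output directory.
#' @param cfg An [eval_config()].
#' @param seed Master seed.
#' @return The `edema_comparison`, invisibly.
#' @export
run_evaluate <- function(features_csv, labels_csv, out_dir,
                         cfg = eval_config(), seed = 1L) {
  feats <- readr::read_csv(features_csv, show_col_types = FALSE)
  labels <- readr::read_csv(labels_csv, show_col_types = FALSE)
  if ("lesion_id" %in% names(labels) && "lesion_id" %in% names(feats)) {
    labels <- labels[match(feats$lesion_id, labels$lesion_id), ]
  }
  cmp <- compare_configurations(feats, labels, cfg = cfg, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(glance(cmp), file.path(out_dir, "delta_table.csv"))
  for (nm in names(cmp$results)) {
    pair <- cmp$results[[nm]]
    jsonlite::write_json(
      list(label = nm,
           semantic = unclass(glance(pair$semantic)),
           combined = unclass(glance(pair$combined)),
           selected_semantic = pair$semantic$selected,
           selected_combined = pair$combined$selected,
           provenance = provenance(seed, strip_classes(cfg))),
      file.path(out_dir, paste0("report_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(cmp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
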