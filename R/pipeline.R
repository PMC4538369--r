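#' Merge DCE and DW voxel feature tables on the common grid
#'
#' Inner join on voxel coordinates `(i, j, k)`: only voxels present in both
#' modalities survive, so the analysis is restricted to tissue covered by
#' both datasets.
#'
#' @param dce_table voxel table from [fit_dce_volume()] (common grid).
#' @param dwi_table voxel table from [fit_dwi_volume()] (same grid).
#' @return Data frame with one row per shared voxel and the 23 feature
#'   columns plus `lesion_id` and coordinates.
#' @export
merge_features <- function(dce_table, dwi_table) {
  stopifnot(all(c("i", "j", "k") %in% names(dce_table)),
            all(c("i", "j", "k") %in% names(dwi_table)))
  dwi_keep <- dwi_table[, c("i", "j", "k", "f", "D_star", "D", "ADC")]
  out <- merge(dce_table, dwi_keep, by = c("i", "j", "k"), sort = TRUE)
  if (!nrow(out)) stop("no voxels shared between the DCE and DW tables", call. = FALSE)
  out
}

#' Run the full phantom-to-classification pipeline
#'
#' Simulates the phantom, coregisters both modalities onto the common
#' analysis grid by trilinear interpolation (nearest neighbour for the
#' lesion mask), fits the extended Tofts model and TIC descriptors plus the
#' two-step IVIM fit voxelwise over the lesion ROIs, merges the feature
#' tables (voxels covered by both modalities only), aggregates to lesion
#' level by medians, and compares DCE-only, DW-only and combined feature
#' sets at both levels. When `out_dir` is given, all intermediate artifacts
#' (NIfTI volumes, CSV tables, JSON report and a run manifest) are written
#' as plain files so each stage can be re-run independently.
#'
#' @param config a [phantom_config]; its `seed` governs all randomness.
#' @param out_dir optional output directory.
#' @param target_voxel common-grid voxel size in mm.
#' @param b_threshold high-b cutoff for the segmented IVIM fit (s/mm^2).
#' @param prevalence_weight weight for the ROC operating point (default:
#'   empirical malignant prevalence).
#' @return A list of class `qmri_run`: `truth`, `grid` (common grid),
#'   `voxel_table`, `lesion_table`, `comparison_voxel`, `comparison_lesion`,
#'   `spearman`, `manifest`.
#' @export
run_pipeline <- function(config = phantom_config(), out_dir = NULL,
                         target_voxel = c(1.5, 1.5, 6), b_threshold = 200,
                         prevalence_weight = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  stages <- list()

  truth <- build_phantom(config)
  dce <- simulate_dce(config, truth)
  dwi <- simulate_dw(config, truth)
  stages$simulate <- list(n_lesions = nrow(truth$lesions),
                          n_voxels_dce = sum(truth$mask_dce > 0),
                          n_voxels_dw = sum(truth$mask_dw > 0))
  if (!is.null(out_dir)) write_phantom(config, truth, dce, dwi, file.path(out_dir, "phantom"))

  grid <- common_grid(config$grid_dce, config$grid_dw, target_voxel)
  dce_c <- resample_trilinear(dce, grid)
  dwi_c <- resample_trilinear(dwi, grid)
  mask <- resample_nearest(truth$mask_dce, config$grid_dce, grid)
  stages$coregister <- list(grid_dims = grid$dims, grid_voxel = grid$voxel,
                            n_mask_voxels = sum(mask > 0))
  if (sum(mask > 0) == 0) stop("coregister: no lesion voxels on the common grid", call. = FALSE)

  dce_tab <- fit_dce_volume(dce_c, mask, config$signal, aif_params(config$dose))
  stages$fit_dce <- list(n_voxels = nrow(dce_tab),
                         n_nonconverged = sum(!dce_tab$converged),
                         n_clipped_frames = sum(dce_tab$n_clipped))
  dwi_tab <- fit_dwi_volume(dwi_c, mask, b_threshold)
  stages$fit_dwi <- list(n_voxels = nrow(dwi_tab),
                         n_flagged = sum(dwi_tab$flag != "ok"))

  voxels <- merge_features(dce_tab, dwi_tab)
  lab <- truth$lesions$label[match(voxels$lesion_id, truth$lesions$lesion_id)]
  voxels$label <- lab
  stages$merge <- list(n_voxels = nrow(voxels))

  lesions <- aggregate_lesions(voxels, feature_set("all"))
  rho <- spearman_matrix(voxels)
  cmp_v <- compare_feature_sets(voxels, "voxel", prevalence_weight = prevalence_weight)
  cmp_l <- compare_feature_sets(lesions, "lesion", prevalence_weight = prevalence_weight)
  stages$classify <- list(
    lesion_auc = vapply(cmp_l$results, function(r) r$roc$auc, numeric(1)),
    voxel_auc = vapply(cmp_v$results, function(r) r$roc$auc, numeric(1)))

  manifest <- list(package = "breastqmri",
                   version = as.character(utils::packageVersion("breastqmri")),
                   seed = config$seed,
                   config = config_to_list(config),
                   target_voxel = target_voxel, b_threshold = b_threshold,
                   stages = stages)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(voxels, file.path(out_dir, "features_voxel.csv"), row.names = FALSE)
    write.csv(lesions, file.path(out_dir, "features_lesion.csv"), row.names = FALSE)
    write.csv(as.data.frame(rho), file.path(out_dir, "spearman.csv"), row.names = TRUE)
    report <- list(
      lesion = lapply(cmp_l$results, summarise_set),
      voxel = lapply(cmp_v$results, summarise_set))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  structure(list(truth = truth, grid = grid, voxel_table = voxels,
                 lesion_table = lesions, spearman = rho,
                 comparison_voxel = cmp_v, comparison_lesion = cmp_l,
                 manifest = manifest),
            class = "qmri_run")
}

summarise_set <- function(r) {
  list(set = r$set, auc = r$roc$auc,
       operating_point = r$roc$operating_point[c("threshold", "tpr", "fpr")],
       misclassified_lesions = r$misclassified,
       percent_correct = if ("percent_correct" %in% names(r$lesions))
         setNames(r$lesions$percent_correct, r$lesions$lesion_id) else NULL)
}

# plain-list view of a phantom_config for the manifest (round-trippable)
config_to_list <- function(config) {
  list(n_lesions_benign = config$n_lesions_benign,
       n_lesions_malignant = config$n_lesions_malignant,
       grid_dce = config$grid_dce[c("voxel", "dims", "origin")],
       grid_dw = config$grid_dw[c("voxel", "dims", "origin")],
       n_timepoints = config$n_timepoints, dt = config$dt,
       b_values = config$b_values, dose = config$dose,
       noise_sigma = config$noise_sigma, noise_model = config$noise_model,
       baseline = config$baseline,
       params = unclass(config$params),
       signal = unclass(config$signal),
       seed = config$seed)
}

#' @export
print.qmri_run <- function(x, ...) {
  cat("breastqmri pipeline run\n")
  cat(sprintf("  %d lesions, %d shared voxels on a %s grid\n",
              nrow(x$truth$lesions), nrow(x$voxel_table),
              paste(x$grid$dims, collapse = " x ")))
  print(x$comparison_lesion)
  print(x$comparison_voxel)
  invisible(x)
}
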