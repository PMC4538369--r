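#' Write a dynamic series as NIfTI-1 with a JSON sidecar
#'
#' The 4th axis is time (DCE) or b-index (DW); voxel size goes into the
#' NIfTI pixdim, while frame times / b-values, the world origin and
#' acquisition metadata go into `<stem>.json` next to the volume.
#'
#' @param series a [dynamic_series].
#' @param stem output path without extension; writes `<stem>.nii.gz` and
#'   `<stem>.json`.
#' @return Invisibly, the NIfTI path.
#' @export
write_series <- function(series, stem) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$data, pixdim = c(series$grid$voxel, 1))
  path <- paste0(stem, ".nii.gz")
  RNifti::writeNifti(img, path)
  side <- list(kind = series$kind, origin = series$grid$origin,
               voxel = series$grid$voxel, frames = series$frames,
               meta = series$meta)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dynamic series written by [write_series()]
#'
#' @param stem path without extension.
#' @return A [dynamic_series].
#' @export
read_series <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  arr <- array(as.numeric(img), dim = dim(img))
  grid <- grid_geometry(side$voxel, dim(arr)[1:3], side$origin)
  meta <- if (is.null(side$meta)) list() else as.list(side$meta)
  dynamic_series(arr, grid, side$frames, side$kind, meta)
}

#' Write a label mask as NIfTI-1 with a JSON sidecar
#'
#' @param mask 3D integer label volume.
#' @param grid its [grid_geometry].
#' @param stem output path without extension.
#' @return Invisibly, the NIfTI path.
#' @export
write_mask <- function(mask, grid, stem) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         pixdim = grid$voxel, datatype = "int16")
  path <- paste0(stem, ".nii.gz")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(kind = "mask", origin = grid$origin, voxel = grid$voxel),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param stem path without extension.
#' @return List with `mask` (3D integer array) and `grid`.
#' @export
read_mask <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  list(mask = array(as.integer(img), dim = dim(img)),
       grid = grid_geometry(side$voxel, dim(img)[1:3], side$origin))
}

#' Write the phantom ground truth and volumes to a directory
#'
#' Emits `dce`/`dwi` series, the lesion masks on both grids, and
#' `ground_truth.csv` (one row per lesion with label and generating
#' parameters).
#'
#' @param config a [phantom_config].
#' @param truth a [build_phantom()] result.
#' @param dce,dwi simulated series from [simulate_dce()]/[simulate_dw()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(config, truth, dce, dwi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series(dce, file.path(dir, "dce"))
  write_series(dwi, file.path(dir, "dwi"))
  write_mask(truth$mask_dce, config$grid_dce, file.path(dir, "mask_dce"))
  write_mask(truth$mask_dw, config$grid_dw, file.path(dir, "mask_dw"))
  write.csv(truth$lesions, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
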