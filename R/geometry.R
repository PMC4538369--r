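#' Grid geometry of an image volume
#'
#' Describes where a 3D voxel grid sits in world space. World coordinates are
#' in millimetres at voxel centres; `origin` is the world position of the
#' centre of voxel `(1,1,1)`. The physical extent of the grid includes the
#' half-voxel margin around the outermost voxel centres.
#'
#' @param voxel numeric length-3, voxel size in mm along x, y, z (> 0).
#' @param dims integer length-3, matrix dimensions (>= 1).
#' @param origin numeric length-3, world mm of the centre of the first voxel.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(voxel, dims, origin = voxel / 2) {
  voxel <- as.numeric(voxel); dims <- as.integer(dims); origin <- as.numeric(origin)
  stopifnot(length(voxel) == 3, length(dims) == 3, length(origin) == 3)
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("voxel sizes must be positive", call. = FALSE)
  if (any(dims < 1L))
    stop("matrix dimensions must be >= 1", call. = FALSE)
  structure(list(voxel = voxel, dims = dims, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("grid_geometry:", paste(x$dims, collapse = " x "), "voxels of",
      paste(signif(x$voxel, 4), collapse = " x "), "mm, origin",
      paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  invisible(x)
}

# world-space extent [lo, hi] per axis, including half-voxel margins
grid_extent <- function(g) {
  lo <- g$origin - g$voxel / 2
  hi <- g$origin + (g$dims - 1) * g$voxel + g$voxel / 2
  rbind(lo = lo, hi = hi)
}

# world coordinates of voxel centres along one axis
grid_axis <- function(g, axis) g$origin[axis] + (seq_len(g$dims[axis]) - 1) * g$voxel[axis]

#' Common grid covering the intersection of two acquisitions
#'
#' Builds the analysis grid onto which both modalities are resampled: a grid
#' at `target_voxel` resolution spanning only the intersection of the two
#' physical extents, so that every voxel of the result is covered by both
#' source volumes (voxels seen by only one dataset are discarded).
#'
#' @param geom_a,geom_b `grid_geometry` of the two source volumes.
#' @param target_voxel numeric length-3 target voxel size in mm; the default
#'   1.5 x 1.5 x 6 mm is the common breast-protocol resolution for a
#'   1.44 x 1.44 x 2 mm DCE / 1.52 x 1.52 x 6 mm DW pair.
#' @return A `grid_geometry` for the common grid.
#' @export
common_grid <- function(geom_a, geom_b, target_voxel = c(1.5, 1.5, 6)) {
  stopifnot(inherits(geom_a, "grid_geometry"), inherits(geom_b, "grid_geometry"))
  target_voxel <- as.numeric(target_voxel)
  if (any(target_voxel <= 0)) stop("target voxel size must be positive", call. = FALSE)
  ea <- grid_extent(geom_a); eb <- grid_extent(geom_b)
  lo <- pmax(ea["lo", ], eb["lo", ])
  hi <- pmin(ea["hi", ], eb["hi", ])
  if (any(hi - lo < target_voxel - 1e-9))
    stop("source volumes have empty (or sub-voxel) physical intersection", call. = FALSE)
  dims <- pmax(1L, as.integer(floor((hi - lo) / target_voxel + 1e-9)))
  grid_geometry(target_voxel, dims, origin = lo + target_voxel / 2)
}

#' A 4D dynamic series (space x time or space x b-value)
#'
#' Common carrier for DCE and DW data: a 4D array with its grid geometry and
#' fourth-axis metadata (frame times in seconds for DCE, b-values in s/mm^2
#' for DW).
#'
#' @param data 3D or 4D numeric array (a 3D array is treated as one frame).
#' @param grid a [grid_geometry].
#' @param frames numeric, one value per 4th-axis entry: frame times (s) for
#'   `kind = "dce"`, b-values (s/mm^2) for `kind = "dwi"`.
#' @param kind `"dce"` or `"dwi"`.
#' @param meta optional named list of acquisition metadata.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, grid, frames, kind = c("dce", "dwi"), meta = list()) {
  kind <- match.arg(kind)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, inherits(grid, "grid_geometry"))
  if (!all(dim(data)[1:3] == grid$dims))
    stop("array dimensions do not match grid geometry", call. = FALSE)
  if (length(frames) != dim(data)[4])
    stop("need one frame time / b-value per 4th-axis entry", call. = FALSE)
  structure(list(data = data, grid = grid, frames = as.numeric(frames),
                 kind = kind, meta = meta),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("dynamic_series (%s): %s, %d frames\n", x$kind,
              paste(dim(x$data)[1:3], collapse = " x "), dim(x$data)[4]))
  print(x$grid)
  invisible(x)
}

# fractional (1-based) source indices of arbitrary world coordinates
world_to_index <- function(g, w) {
  sweep(sweep(w, 2, g$origin, "-"), 2, g$voxel, "/") + 1
}

# world coordinates of every voxel centre of a grid (n x 3, x fastest)
grid_centres <- function(g) {
  cbind(rep(grid_axis(g, 1), times = g$dims[2] * g$dims[3]),
        rep(rep(grid_axis(g, 2), each = g$dims[1]), times = g$dims[3]),
        rep(grid_axis(g, 3), each = g$dims[1] * g$dims[2]))
}

# trilinear interpolation of a 3D array at fractional 1-based indices;
# indices are clamped to the voxel-centre range (callers have already
# verified the points lie inside the physical extent, i.e. at most half a
# voxel beyond the outermost centres).
trilinear_sample <- function(vol, idx) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(idx[, 1], d[1]); y <- cl(idx[, 2], d[2]); z <- cl(idx[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0[d[1] == 1L] <- 1L
  y0 <- pmin(floor(y), d[2] - 1L); y0[d[2] == 1L] <- 1L
  z0 <- pmin(floor(z), d[3] - 1L); z0[d[3] == 1L] <- 1L
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
  c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
  c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
  c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

check_target_inside <- function(source_grid, target) {
  es <- grid_extent(source_grid); et <- grid_extent(target)
  if (any(et["lo", ] < es["lo", ] - 1e-9) || any(et["hi", ] > es["hi", ] + 1e-9))
    stop("target grid exceeds source physical extent; no extrapolation is performed",
         call. = FALSE)
}

#' Resample a dynamic series onto a target grid by trilinear interpolation
#'
#' Each frame is interpolated independently; frame metadata is preserved.
#' The target must lie inside the source physical extent: no extrapolation.
#' Interpolated values are convex combinations of the eight surrounding
#' voxels, so each frame's output range stays within its input range.
#'
#' @param series a [dynamic_series].
#' @param target a [grid_geometry], typically from [common_grid()].
#' @return A [dynamic_series] on `target`.
#' @export
resample_trilinear <- function(series, target) {
  stopifnot(inherits(series, "dynamic_series"), inherits(target, "grid_geometry"))
  check_target_inside(series$grid, target)
  idx <- world_to_index(series$grid, grid_centres(target))
  nf <- dim(series$data)[4]
  out <- array(NA_real_, c(target$dims, nf))
  for (f in seq_len(nf))
    out[, , , f] <- array(trilinear_sample(series$data[, , , f], idx), target$dims)
  dynamic_series(out, target, series$frames, series$kind, series$meta)
}

#' Resample a label volume by nearest neighbour
#'
#' ROI masks and lesion label maps keep integer semantics, so they are
#' resampled by nearest neighbour rather than trilinear weights.
#'
#' @param mask 3D array of integer labels (0 = background).
#' @param grid `grid_geometry` of `mask`.
#' @param target target `grid_geometry` (must lie inside `grid`'s extent).
#' @return 3D array of labels on `target`.
#' @export
resample_nearest <- function(mask, grid, target) {
  stopifnot(length(dim(mask)) == 3L, inherits(grid, "grid_geometry"),
            inherits(target, "grid_geometry"))
  check_target_inside(grid, target)
  idx <- world_to_index(grid, grid_centres(target))
  d <- dim(mask)
  ii <- pmin(pmax(round(idx[, 1]), 1), d[1])
  jj <- pmin(pmax(round(idx[, 2]), 1), d[2])
  kk <- pmin(pmax(round(idx[, 3]), 1), d[3])
  array(mask[cbind(ii, jj, kk)], target$dims)
}
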