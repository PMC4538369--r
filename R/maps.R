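#' Voxelwise DCE analysis over a lesion mask
#'
#' For every voxel with a non-zero mask label: converts the signal
#' time-course to gadolinium concentration, fits the extended Tofts model,
#' and computes the 17 model-free TIC descriptors. Non-convergent voxels
#' keep missing kinetic parameters (propagated, not raised).
#'
#' @param series a DCE [dynamic_series] (frame times in seconds).
#' @param mask 3D label volume on the same grid (0 = background; other
#'   values are lesion ids).
#' @param sm a [signal_model_params].
#' @param aif an [aif_params].
#' @param n_baseline number of pre-contrast frames.
#' @return Data frame with one row per mask voxel: `i, j, k` (1-based array
#'   indices), `lesion_id`, `Ktrans`, `kep`, `vp` (min^-1 / min^-1 / -),
#'   `rss`, `converged`, `n_clipped`, and the 17 TIC columns.
#' @export
fit_dce_volume <- function(series, mask, sm = signal_model_params(),
                           aif = aif_params(), n_baseline = 1) {
  stopifnot(inherits(series, "dynamic_series"), series$kind == "dce",
            all(dim(mask) == series$grid$dims))
  t_sec <- series$frames
  dt <- if (!is.null(series$meta$dt)) series$meta$dt else diff(t_sec)[1]
  # bolus arrives at the start of the first postcontrast frame
  tau_min <- (t_sec - (t_sec[n_baseline] + dt)) / 60
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask selects no voxels", call. = FALSE)
  nf <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nf)
  lin <- which(mask > 0)

  rows <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    tic <- flat[lin[r], ]
    conc <- signal_to_concentration(tic, sm, n_baseline)
    fit <- fit_tofts(as.numeric(conc), tau_min, aif)
    feats <- tic_features(tic, t_sec, as.numeric(conc), n_baseline)
    rows[[r]] <- c(i = unname(idx[r, 1]), j = unname(idx[r, 2]), k = unname(idx[r, 3]),
                   lesion_id = mask[lin[r]],
                   Ktrans = unname(fit$par["ktrans"]), kep = unname(fit$par["kep"]),
                   vp = unname(fit$par["vp"]), rss = fit$rss,
                   converged = as.numeric(fit$converged),
                   n_clipped = attr(conc, "n_clipped"), feats)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$converged <- as.logical(out$converged)
  out
}

#' Voxelwise DW analysis over a lesion mask
#'
#' Runs the segmented two-step IVIM fit and the monoexponential ADC for
#' every voxel with a non-zero mask label.
#'
#' @param series a DW [dynamic_series] (b-values as frames).
#' @param mask 3D label volume on the same grid.
#' @param threshold high-b cutoff in s/mm^2 for the segmented fit.
#' @return Data frame with one row per mask voxel: `i, j, k`, `lesion_id`,
#'   `f`, `D_star`, `D`, `ADC` (mm^2/s), `rss`, `converged`, `flag`.
#' @export
fit_dwi_volume <- function(series, mask, threshold = 200) {
  stopifnot(inherits(series, "dynamic_series"), series$kind == "dwi",
            all(dim(mask) == series$grid$dims))
  b <- series$frames
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask selects no voxels", call. = FALSE)
  nf <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nf)
  lin <- which(mask > 0)

  rows <- vector("list", nrow(idx))
  flags <- character(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    fit <- fit_ivim(flat[lin[r], ], b, threshold)
    flags[r] <- fit$flag
    rows[[r]] <- c(i = unname(idx[r, 1]), j = unname(idx[r, 2]), k = unname(idx[r, 3]),
                   lesion_id = mask[lin[r]],
                   f = unname(fit$par["f"]), D_star = unname(fit$par["D_star"]),
                   D = unname(fit$par["D"]), ADC = unname(fit$par["ADC"]),
                   rss = fit$rss, converged = as.numeric(fit$converged))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$converged <- as.logical(out$converged)
  out$flag <- flags
  out
}
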