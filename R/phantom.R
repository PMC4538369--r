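#' Class-conditional tissue parameter distributions
#'
#' Log-normal distributions, per class and per parameter, from which the
#' phantom draws lesion-level kinetic and diffusion parameters. Each entry
#' is `c(median, sdlog)`: the natural-scale median and the log-scale
#' standard deviation across lesions (`sdlog = 0` gives a degenerate,
#' zero-variance distribution). Defaults encode the expected contrast
#' between benign and malignant breast tissue — malignant lesions have
#' higher Ktrans, kep, vp, perfusion fraction f and pseudodiffusivity D*
#' and lower tissue diffusivity D — with magnitudes typical of breast DCE
#' and IVIM literature. These are configuration data, not code constants:
#' effect sizes are experiment inputs.
#'
#' @param benign,malignant named lists of `c(median, sdlog)` for `ktrans`
#'   (min^-1), `kep` (min^-1), `vp` (-), `f` (-), `d_star` (mm^2/s),
#'   `d` (mm^2/s).
#' @param voxel_sdlog log-scale SD of the within-lesion voxel-to-voxel
#'   heterogeneity multiplier.
#' @return A list of class `class_params`.
#' @export
class_params <- function(
    benign = list(ktrans = c(0.08, 0.3), kep = c(0.45, 0.3), vp = c(0.02, 0.3),
                  f = c(0.06, 0.3), d_star = c(8e-3, 0.3), d = c(1.6e-3, 0.15)),
    malignant = list(ktrans = c(0.35, 0.3), kep = c(1.3, 0.3), vp = c(0.06, 0.3),
                     f = c(0.12, 0.3), d_star = c(15e-3, 0.3), d = c(1.0e-3, 0.15)),
    voxel_sdlog = 0.1) {
  need <- c("ktrans", "kep", "vp", "f", "d_star", "d")
  for (cl in list(benign, malignant)) {
    if (!all(need %in% names(cl))) stop("missing class parameter entries", call. = FALSE)
    if (any(vapply(cl, function(v) v[1] <= 0 || v[2] < 0, logical(1))))
      stop("parameter medians must be positive, sdlog non-negative", call. = FALSE)
  }
  structure(list(benign = benign, malignant = malignant,
                 voxel_sdlog = voxel_sdlog), class = "class_params")
}

#' Expected parameter means of a class distribution
#'
#' Natural-scale means of the lesion-level log-normal draws,
#' `median * exp(sdlog^2 / 2)` per parameter.
#'
#' @param params a [class_params].
#' @param class_label `"benign"` or `"malignant"`.
#' @return Named numeric vector of means.
#' @export
class_param_means <- function(params, class_label = c("benign", "malignant")) {
  class_label <- match.arg(class_label)
  vapply(params[[class_label]], function(v) v[1] * exp(v[2]^2 / 2), numeric(1))
}

#' Phantom configuration
#'
#' Defines the synthetic cohort and the two emulated acquisitions: a DCE
#' series of `n_timepoints` frames every `dt` seconds on a fine
#' anisotropic grid, and a multi-b DW series on a coarser thick-slice grid,
#' with the contrast dose, noise level and class-conditional tissue
#' parameters. Defaults mirror a 1.5 T breast protocol (10 frames at 56 s,
#' b = 0...1000 s/mm^2, 0.1 mL/kg Gd-DOTA, 1.44 x 1.44 x 2 mm DCE vs
#' 1.52 x 1.52 x 6 mm DW voxels) with a cohort of 16 benign and 15
#' malignant lesions; matrix sizes are kept small enough that the full
#' pipeline runs in minutes.
#'
#' @param n_lesions_benign,n_lesions_malignant lesion counts per class.
#' @param grid_dce,grid_dw [grid_geometry] of the two acquisitions.
#' @param n_timepoints number of DCE frames (>= 2); frame 1 is pre-contrast.
#' @param dt seconds between DCE frames (> 0).
#' @param b_values b-values in s/mm^2, non-negative and strictly increasing.
#' @param dose contrast dose in mL/kg.
#' @param noise_sigma noise SD as a fraction of the baseline signal.
#' @param noise_model `"rician"` (magnitude MRI) or `"gaussian"` (for
#'   analytic tests).
#' @param baseline baseline signal level (arbitrary units).
#' @param params a [class_params].
#' @param signal a [signal_model_params].
#' @param seed integer seed controlling every random draw.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_lesions_benign = 16, n_lesions_malignant = 15,
                           grid_dce = grid_geometry(c(1.44, 1.44, 2), c(48, 48, 12)),
                           grid_dw = grid_geometry(c(1.52, 1.52, 6), c(46, 46, 4)),
                           n_timepoints = 10, dt = 56,
                           b_values = c(0, 50, 100, 150, 400, 800, 1000),
                           dose = 0.1, noise_sigma = 0.02,
                           noise_model = c("rician", "gaussian"),
                           baseline = 100,
                           params = class_params(),
                           signal = signal_model_params(),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_timepoints < 2) stop("need at least 2 time points", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(b_values < 0) || any(diff(b_values) <= 0))
    stop("b_values must be non-negative and strictly increasing", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  stopifnot(inherits(grid_dce, "grid_geometry"), inherits(grid_dw, "grid_geometry"),
            inherits(params, "class_params"), inherits(signal, "signal_model_params"))
  structure(list(n_lesions_benign = n_lesions_benign,
                 n_lesions_malignant = n_lesions_malignant,
                 grid_dce = grid_dce, grid_dw = grid_dw,
                 n_timepoints = as.integer(n_timepoints), dt = dt,
                 b_values = b_values, dose = dose,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 baseline = baseline, params = params, signal = signal,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Draw lesion-level tissue parameters for one lesion
#'
#' One log-normal draw per parameter from the class-conditional
#' distributions in `config$params`. With `sdlog = 0` every draw equals the
#' class median.
#'
#' @param config a [phantom_config].
#' @param class_label `"benign"` or `"malignant"`.
#' @return List with `tofts` (ktrans, kep, vp) and `ivim` (f, d_star, d).
#' @export
sample_lesion_parameters <- function(config, class_label) {
  if (!class_label %in% c("benign", "malignant"))
    stop("unknown class label: ", class_label, call. = FALSE)
  cp <- config$params[[class_label]]
  draw <- vapply(cp, function(v) stats::rlnorm(1, meanlog = log(v[1]), sdlog = v[2]),
                 numeric(1))
  draw["vp"] <- min(draw["vp"], 1)
  draw["f"] <- min(draw["f"], 1)
  list(tofts = draw[c("ktrans", "kep", "vp")], ivim = draw[c("f", "d_star", "d")])
}

# ellipsoid membership of world points (n x 3) given centre and semiaxes (mm)
in_ellipsoid <- function(w, centre, semi) {
  rowSums(sweep(sweep(w, 2, centre, "-"), 2, semi, "/")^2) <= 1
}

#' Build the digital phantom ground truth
#'
#' Places non-overlapping axis-aligned ellipsoidal lesions on a jittered
#' lattice inside the volume shared by the two acquisition grids, draws
#' class-conditional lesion parameters, applies within-lesion log-normal
#' voxel heterogeneity, and rasterises lesion label masks and per-voxel
#' parameter maps on both grids. All randomness is governed by
#' `config$seed`.
#'
#' @param config a [phantom_config].
#' @return A list of class `phantom_truth`: `lesions` (data frame with id,
#'   label, centre, semiaxes and lesion-level parameters), `mask_dce`,
#'   `mask_dw` (label volumes), and per-voxel maps `tofts_dce` (arrays
#'   ktrans/kep/vp on the DCE grid) and `ivim_dw` (arrays f/d_star/d on the
#'   DW grid).
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n_total <- config$n_lesions_benign + config$n_lesions_malignant
  ea <- grid_extent(config$grid_dce); eb <- grid_extent(config$grid_dw)
  lo <- pmax(ea["lo", ], eb["lo", ]); hi <- pmin(ea["hi", ], eb["hi", ])
  if (any(hi <= lo)) stop("acquisition grids do not overlap", call. = FALSE)

  # jittered in-plane lattice; lesion centres share the axial mid-plane band
  semi_lo <- c(3.2, 3.2, 5.5); semi_hi <- c(4.5, 4.5, 8)
  margin <- semi_hi[1:2] + 1
  nx <- ceiling(sqrt(n_total))
  gx <- seq(lo[1] + margin[1], hi[1] - margin[1], length.out = nx)
  gy <- seq(lo[2] + margin[2], hi[2] - margin[2], length.out = ceiling(n_total / nx))
  slots <- expand.grid(x = gx, y = gy)
  if (nrow(slots) < n_total)
    stop("volume too small to place the requested lesions without overlap", call. = FALSE)
  slots <- slots[seq_len(n_total), , drop = FALSE]
  zc <- (lo[3] + hi[3]) / 2

  labels <- sample(rep(c("benign", "malignant"),
                       c(config$n_lesions_benign, config$n_lesions_malignant)))
  # jitter bounded by half the lattice gap (non-overlap) and capped at 2 mm
  # so edge slots stay inside the placement margins
  jit <- min(diff(gx)[1] %||% 4, diff(gy)[1] %||% 4) / 2 - semi_hi[1] - 0.25
  jit <- max(min(jit, 2), 0)

  lesions <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    p <- sample_lesion_parameters(config, labels[i])
    data.frame(lesion_id = i, label = labels[i],
               cx = slots$x[i] + runif(1, -jit, jit),
               cy = slots$y[i] + runif(1, -jit, jit),
               cz = zc + runif(1, -1, 1),
               sx = runif(1, semi_lo[1], semi_hi[1]),
               sy = runif(1, semi_lo[2], semi_hi[2]),
               sz = runif(1, semi_lo[3], semi_hi[3]),
               ktrans = p$tofts[["ktrans"]], kep = p$tofts[["kep"]],
               vp = p$tofts[["vp"]], f = p$ivim[["f"]],
               d_star = p$ivim[["d_star"]], d = p$ivim[["d"]])
  }))

  rasterise <- function(grid, pars) {
    w <- grid_centres(grid)
    mask <- array(0L, grid$dims)
    maps <- lapply(pars, function(...) array(0, grid$dims))
    names(maps) <- pars
    vs <- config$params$voxel_sdlog
    for (i in seq_len(nrow(lesions))) {
      inside <- which(in_ellipsoid(w, c(lesions$cx[i], lesions$cy[i], lesions$cz[i]),
                                   c(lesions$sx[i], lesions$sy[i], lesions$sz[i])))
      if (!length(inside)) next
      mask[inside] <- lesions$lesion_id[i]
      for (p in pars) {
        v <- lesions[[p]][i] * stats::rlnorm(length(inside), 0, vs)
        if (p %in% c("vp", "f")) v <- pmin(v, 1)
        maps[[p]][inside] <- v
      }
    }
    list(mask = mask, maps = maps)
  }
  dce <- rasterise(config$grid_dce, c("ktrans", "kep", "vp"))
  dw <- rasterise(config$grid_dw, c("f", "d_star", "d"))

  empty <- setdiff(lesions$lesion_id,
                   union(unique(as.vector(dce$mask)), unique(as.vector(dw$mask))))
  if (length(empty)) warning("lesions with no voxels on either grid: ",
                             paste(empty, collapse = ", "))

  structure(list(lesions = lesions, mask_dce = dce$mask, mask_dw = dw$mask,
                 tofts_dce = dce$maps, ivim_dw = dw$maps, config = config),
            class = "phantom_truth")
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || is.na(a[1])) b else a

# magnitude-MRI noise: Rician via two Gaussian channels, or plain Gaussian
add_noise <- function(x, sigma, model) {
  if (sigma <= 0) return(x)
  n <- length(x)
  if (model == "rician")
    sqrt((x + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  else x + rnorm(n, 0, sigma)
}

#' Simulate the DCE acquisition of a phantom
#'
#' For each lesion voxel the extended Tofts concentration time-course is
#' generated from the ground-truth parameters ([tofts_forward()]) and
#' converted to spoiled-gradient-echo signal; background voxels carry the
#' constant baseline signal. Frame 1 is pre-contrast; the bolus arrives at
#' the start of frame 2. Magnitude noise at `noise_sigma * baseline` is
#' added.
#'
#' @param config a [phantom_config].
#' @param truth a [build_phantom()] result.
#' @return A [dynamic_series] (`kind = "dce"`) with frame times in seconds.
#' @export
simulate_dce <- function(config, truth) {
  stopifnot(inherits(config, "phantom_config"), inherits(truth, "phantom_truth"))
  set.seed(config$seed + 1L)
  km <- truth$tofts_dce
  if (any(km$ktrans < 0) || any(km$kep < 0))
    stop("non-physical kinetic parameters (negative ktrans or kep)", call. = FALSE)
  if (any(km$vp < 0 | km$vp > 1)) stop("vp must lie in [0, 1]", call. = FALSE)
  t_sec <- (seq_len(config$n_timepoints) - 1) * config$dt
  tau_min <- (t_sec - config$dt) / 60      # minutes since injection
  aif <- aif_params(dose = config$dose)
  sm <- config$signal
  m0 <- config$baseline / spgr_factor(1000 / sm$T1_0, sm)

  nvox <- prod(config$grid_dce$dims)
  sig <- matrix(config$baseline, nrow = nvox, ncol = config$n_timepoints)
  idx <- which(truth$mask_dce > 0)
  for (v in idx) {
    ct <- tofts_forward(tau_min, km$ktrans[v], km$kep[v], km$vp[v], aif)
    sig[v, ] <- concentration_to_signal(ct, sm, m0)
  }
  sig <- add_noise(sig, config$noise_sigma * config$baseline, config$noise_model)
  dynamic_series(array(sig, c(config$grid_dce$dims, config$n_timepoints)),
                 config$grid_dce, t_sec, "dce",
                 meta = list(dt = config$dt, dose = config$dose,
                             TR = sm$TR, flip_angle = sm$flip_angle,
                             T1_0 = sm$T1_0, r1 = sm$r1, n_baseline = 1))
}

#' Simulate the DW acquisition of a phantom
#'
#' For each lesion voxel the biexponential IVIM decay
#' `S(b) = S0 (f exp(-b D*) + (1-f) exp(-b D))` is generated from the
#' ground-truth parameters; background voxels carry a flat baseline (inert
#' outside the ROIs). Magnitude noise at `noise_sigma * baseline` is added.
#'
#' @param config a [phantom_config].
#' @param truth a [build_phantom()] result.
#' @return A [dynamic_series] (`kind = "dwi"`) with b-values as frames.
#' @export
simulate_dw <- function(config, truth) {
  stopifnot(inherits(config, "phantom_config"), inherits(truth, "phantom_truth"))
  set.seed(config$seed + 2L)
  im <- truth$ivim_dw
  if (any(im$f < 0 | im$f > 1)) stop("perfusion fraction f must lie in [0, 1]", call. = FALSE)
  if (any(im$d < 0) || any(im$d_star < 0))
    stop("diffusivities must be non-negative", call. = FALSE)
  b <- config$b_values
  nvox <- prod(config$grid_dw$dims)
  sig <- matrix(config$baseline, nrow = nvox, ncol = length(b))
  idx <- which(truth$mask_dw > 0)
  for (v in idx) {
    sig[v, ] <- config$baseline *
      (im$f[v] * exp(-b * im$d_star[v]) + (1 - im$f[v]) * exp(-b * im$d[v]))
  }
  sig <- add_noise(sig, config$noise_sigma * config$baseline, config$noise_model)
  dynamic_series(array(sig, c(config$grid_dw$dims, length(b))),
                 config$grid_dw, b, "dwi", meta = list(b_values = b))
}
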