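#' Monoexponential ADC from a multi-b diffusion decay
#'
#' Apparent diffusion coefficient by log-linear least squares: the slope of
#' `-ln(S/S0)` versus b over all b-values, with `S0` taken from the b = 0
#' measurement. With exactly two b-values this reduces to the closed form
#' `ADC = ln(S0/Sb) / b`.
#'
#' @param S signal per b-value (all > 0).
#' @param b b-values in s/mm^2 (must include 0).
#' @return List with `ADC` (mm^2/s) and `S0`.
#' @export
adc_monoexp <- function(S, b) {
  stopifnot(length(S) == length(b))
  if (length(b) < 2) stop("need at least 2 b-values", call. = FALSE)
  if (!any(b == 0)) stop("b-values must include b = 0", call. = FALSE)
  if (any(!is.finite(S)) || any(S <= 0)) stop("signals must be positive", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, b), log(S))
  list(ADC = -unname(fit$coefficients[2]), S0 = S[which(b == 0)[1]])
}

#' Tissue diffusivity from the high-b monoexponential regime
#'
#' At b-values well above the pseudodiffusion scale the IVIM decay is
#' monoexponential in the tissue diffusivity D, `S_high = S0 * exp(-b D)`.
#' D is estimated by log-linear least squares on the b-values strictly above
#' `threshold` (default 200 s/mm^2), together with the extrapolated b = 0
#' intercept.
#'
#' @param S signal per b-value.
#' @param b b-values in s/mm^2.
#' @param threshold high-b cutoff in s/mm^2; only `b > threshold` is used.
#' @return List with `D` (mm^2/s) and `intercept` (extrapolated signal at
#'   b = 0).
#' @export
fit_D_high_b <- function(S, b, threshold = 200) {
  stopifnot(length(S) == length(b))
  idx <- which(b > threshold)
  if (length(idx) < 2) stop("need at least 2 b-values above the threshold", call. = FALSE)
  if (any(!is.finite(S[idx])) || any(S[idx] <= 0))
    stop("signals must be positive", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, b[idx]), log(S[idx]))
  list(D = -unname(fit$coefficients[2]), intercept = exp(unname(fit$coefficients[1])))
}

#' Segmented two-step IVIM fit
#'
#' Fits the biexponential intravoxel-incoherent-motion model
#' `S(b) = S0 * (f * exp(-b D*) + (1 - f) * exp(-b D))` in two steps, the
#' standard remedy for the ill-conditioning of the free three-parameter fit:
#' \enumerate{
#'   \item D is fixed by the high-b monoexponential fit ([fit_D_high_b()]);
#'   \item f and D* are estimated by bounded nonlinear least squares of the
#'     full biexponential over all b-values, with D held fixed and S0 fixed
#'     at the measured b = 0 signal.
#' }
#' Initialisation: `f0 = 1 - intercept/S0` from the high-b extrapolation,
#' `D*0 = 10 D`. Bounds: f in \[0, 1\], D* in \[D, 0.5\] mm^2/s. The
#' monoexponential ADC over all b-values is reported alongside. A fitted
#' `D* < D` or a non-convergent step 2 is flagged, not raised.
#'
#' @param S signal per b-value (b = 0 required).
#' @param b b-values in s/mm^2.
#' @param threshold high-b cutoff for step 1 (s/mm^2).
#' @return An object of class `ivim_fit` with `par` (f, D_star, D, ADC, S0),
#'   `rss`, `converged`, `flag` (`"ok"`, `"degenerate"`, `"dstar_le_D"` or
#'   `"not_converged"`), `fitted`, and the inputs.
#' @export
fit_ivim <- function(S, b, threshold = 200) {
  stopifnot(length(S) == length(b))
  if (!any(b == 0)) stop("b-values must include b = 0", call. = FALSE)
  if (any(!is.finite(S)) || any(S <= 0)) stop("signals must be positive", call. = FALSE)
  S0 <- S[which(b == 0)[1]]
  adc <- adc_monoexp(S, b)$ADC
  step1 <- fit_D_high_b(S, b, threshold)
  D <- max(step1$D, 0)

  # near-constant decay: D ~ 0 and nothing for the biexponential to explain
  if (stats::sd(S) / mean(S) < 1e-10) {
    out <- list(par = c(f = NA_real_, D_star = NA_real_, D = D, ADC = adc, S0 = S0),
                rss = NA_real_, converged = FALSE, flag = "degenerate",
                fitted = rep(S0, length(b)), b = b, S = S, threshold = threshold)
    return(structure(out, class = "ivim_fit"))
  }

  lower <- c(f = 0, D_star = max(D, 1e-6))
  upper <- c(f = 1, D_star = 0.5)
  start <- c(f = min(max(1 - step1$intercept / S0, 1e-3), 0.5),
             D_star = min(max(10 * D, lower["D_star"] * 1.01), 0.4))
  model <- function(p) S0 * (p[1] * exp(-b * p[2]) + (1 - p[1]) * exp(-b * D))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) S - model(p),
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(par = c(f = NA_real_, D_star = NA_real_, D = D, ADC = adc, S0 = S0),
                rss = NA_real_, converged = FALSE, flag = "not_converged",
                fitted = rep(NA_real_, length(b)), b = b, S = S, threshold = threshold)
    return(structure(out, class = "ivim_fit"))
  }
  f <- unname(fit$par[1]); dstar <- unname(fit$par[2])
  flag <- if (!(fit$info %in% 1:4)) "not_converged"
          else if (dstar < D) "dstar_le_D" else "ok"
  structure(list(par = c(f = f, D_star = dstar, D = D, ADC = adc, S0 = S0),
                 rss = sum(fit$fvec^2), converged = fit$info %in% 1:4,
                 flag = flag, fitted = model(fit$par), b = b, S = S,
                 threshold = threshold),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat("Two-step IVIM fit\n")
  cat(sprintf("  f = %.4g, D* = %.4g mm^2/s, D = %.4g mm^2/s, ADC = %.4g mm^2/s\n",
              x$par["f"], x$par["D_star"], x$par["D"], x$par["ADC"]))
  cat(sprintf("  RSS = %.4g over %d b-values (high-b threshold %g), flag: %s\n",
              x$rss, length(x$b), x$threshold, x$flag))
  invisible(x)
}

#' @export
coef.ivim_fit <- function(object, ...) object$par

#' @export
fitted.ivim_fit <- function(object, ...) object$fitted

#' @export
residuals.ivim_fit <- function(object, ...) object$S - object$fitted

#' @export
predict.ivim_fit <- function(object, b = object$b, ...) {
  p <- object$par
  p["S0"] * (p["f"] * exp(-b * p["D_star"]) + (1 - p["f"]) * exp(-b * p["D"]))
}
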