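#' Model-free time-intensity-curve descriptors
#'
#' Computes the seventeen semiquantitative shape descriptors of a DCE
#' time-intensity curve (TIC). The curve is split at the enhancement peak:
#' the wash-in segment runs from the first post-contrast frame through the
#' peak, the wash-out segment from the peak through the last frame. Slopes
#' and intercepts are ordinary least-squares lines on those segments in
#' signal units versus seconds.
#'
#' Descriptors:
#' \describe{
#'   \item{SB}{basal signal, mean of the `n_baseline` pre-contrast frames.}
#'   \item{MSD}{maximum signal difference, `max(S) - SB`.}
#'   \item{TTP}{time to peak (s), the frame time at maximum signal.}
#'   \item{WIS, WII}{wash-in OLS slope (s^-1) and intercept.}
#'   \item{WOS, WOI}{wash-out OLS slope (s^-1) and intercept.}
#'   \item{WOS.WIS, WOI.WII}{segment slope and intercept ratios.}
#'   \item{AUC}{trapezoidal area under the signal-enhancement curve `S - SB`.}
#'   \item{AUCWI, AUCWO}{trapezoidal area under the gadolinium concentration
#'     curve over the post-injection window, split at the peak
#'     (s mmol L^-1); their sum is the total post-injection area.}
#'   \item{AUCWO.AUCWI}{wash-out / wash-in concentration-area ratio.}
#'   \item{HR}{height ratio `(S_last - SB) / MSD`, persistence of
#'     enhancement at the end of the acquisition.}
#'   \item{PI}{perfusion index: enhancement AUC normalised by the
#'     observation interval.}
#'   \item{SOD}{sum of intensity differences, `sum(S - SB)`.}
#'   \item{VES}{variance of the successive frame-to-frame enhancement
#'     slopes (s^-1) over the post-injection window.}
#' }
#' Ratios with a zero (or undefined) denominator are returned as `NA`, not
#' errors; a segment with fewer than two frames has slope 0 and intercept
#' `NA`.
#'
#' @param tic signal time-course, one value per frame.
#' @param t frame times in seconds (increasing).
#' @param conc gadolinium concentration per frame (mmol/L), e.g. from
#'   [signal_to_concentration()]; used for AUCWI/AUCWO.
#' @param n_baseline number of pre-contrast frames (default 1).
#' @return Named numeric vector of the 17 descriptors.
#' @export
tic_features <- function(tic, t, conc, n_baseline = 1) {
  n <- length(tic)
  if (n < 3) stop("need at least 3 frames", call. = FALSE)
  stopifnot(length(t) == n, length(conc) == n, n_baseline >= 1, n_baseline < n)
  if (any(diff(t) <= 0)) stop("frame times must be increasing", call. = FALSE)

  sb <- mean(tic[seq_len(n_baseline)])
  enh <- tic - sb
  msd <- max(tic) - sb
  p <- which.max(tic)
  ttp <- t[p]

  ols <- function(idx) {
    if (length(idx) < 2) return(list(slope = 0, intercept = NA_real_))
    fit <- stats::lm.fit(cbind(1, t[idx]), tic[idx])
    list(slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
  }
  wi_idx <- if (p >= n_baseline + 1) seq(n_baseline + 1, p) else integer(0)
  wi <- ols(wi_idx)
  wo <- ols(seq(max(p, n_baseline), n))

  trapz <- function(x, y) if (length(x) < 2) 0 else sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  auc <- trapz(t, enh)
  win <- n_baseline:n                      # post-injection window incl. last baseline frame
  rise <- win[win <= max(p, n_baseline)]
  aucwi <- trapz(t[rise], conc[rise])
  aucwo <- trapz(t[max(p, n_baseline):n], conc[max(p, n_baseline):n])

  ratio <- function(num, den) if (!is.finite(den) || den == 0) NA_real_ else num / den
  post_slopes <- diff(tic[win]) / diff(t[win])

  c(SB = sb, MSD = msd, TTP = ttp,
    WIS = wi$slope, WOS = wo$slope,
    WII = wi$intercept, WOI = wo$intercept,
    WOS.WIS = ratio(wo$slope, wi$slope),
    WOI.WII = ratio(wo$intercept, wi$intercept),
    AUC = auc, AUCWI = aucwi, AUCWO = aucwo,
    AUCWO.AUCWI = ratio(aucwo, aucwi),
    HR = ratio(tic[n] - sb, msd),
    PI = auc / (t[n] - t[1]),
    SOD = sum(enh),
    VES = if (length(post_slopes) >= 2) var(post_slopes) else NA_real_)
}

# canonical names of the 17 TIC descriptors, in table order
tic_feature_names <- function() {
  c("WOS.WIS", "WOI.WII", "AUCWI", "AUCWO", "AUCWO.AUCWI", "HR", "TTP",
    "MSD", "AUC", "SB", "WIS", "WII", "WOS", "WOI", "VES", "PI", "SOD")
}
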