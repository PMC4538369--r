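# Independent oracles used across tests.

# numerical convolution oracle for the extended Tofts model:
# Ct(t) = integral_0^t Cp(u) Ktrans exp(-kep (t-u)) du + vp Cp(t),
# by adaptive quadrature, independent of the closed form in the package.
tofts_quadrature <- function(t, ktrans, kep, vp, aif = aif_params()) {
  cp <- function(u) aif$dose * (aif$a1 * exp(-aif$m1 * u) + aif$a2 * exp(-aif$m2 * u))
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    conv <- stats::integrate(function(u) cp(u) * ktrans * exp(-kep * (ti - u)),
                             0, ti, rel.tol = 1e-10, abs.tol = 1e-12)$value
    conv + vp * cp(ti)
  }, numeric(1))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# tiny phantom configuration used where the full cohort is not needed
small_config <- function(seed = 11, noise_sigma = 0, ...) {
  phantom_config(n_lesions_benign = 3, n_lesions_malignant = 3,
                 grid_dce = grid_geometry(c(1.44, 1.44, 2), c(32, 32, 12)),
                 grid_dw = grid_geometry(c(1.52, 1.52, 6), c(30, 30, 4)),
                 noise_sigma = noise_sigma, seed = seed, ...)
}

# a feature table with a prescribed class separation on chosen columns
synthetic_table <- function(n_per_class = 40, sep_cols, all_cols = feature_set("all"),
                            delta = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  tab <- as.data.frame(matrix(rnorm(n * length(all_cols)), n,
                              dimnames = list(NULL, all_cols)))
  tab$label <- rep(c("benign", "malignant"), each = n_per_class)
  tab$lesion_id <- seq_len(n)
  for (cc in sep_cols) tab[[cc]] <- tab[[cc]] + delta * (tab$label == "malignant")
  tab
}
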