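---
title: "Models and methods in breastqmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in breastqmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastqmri)
```

`breastqmri` implements a multiparametric analysis of paired breast MRI
acquisitions: a dynamic contrast-enhanced (DCE) T1-weighted series and a
multi-b diffusion-weighted (DW) series, reduced voxel by voxel to kinetic,
semiquantitative and diffusion parameters, and combined into a
benign/malignant lesion classifier. This vignette records the models, the
tunable parameters, the numerical choices, and what the synthetic phantom
does and does not establish.

## Pharmacokinetic model

Tissue gadolinium concentration follows the extended Tofts model,

$$C_t(t) = K^{trans} \int_0^t C_p(u)\, e^{-k_{ep}(t-u)}\, du + v_p\, C_p(t),$$

with $K^{trans}$ (min⁻¹) the plasma-to-EES transfer constant, $k_{ep}$
(min⁻¹) the EES-to-plasma rate constant, and $v_p$ the plasma volume
fraction. The arterial input $C_p$ is the Weinmann population biexponential
$C_p(t) = d\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ with $a_1 = 3.99$,
$a_2 = 4.78$ kg/L, $m_1 = 0.144$, $m_2 = 0.0111$ min⁻¹ and dose $d$ in
mL/kg. Because both the AIF and the kernel are exponentials, the
convolution has a closed form, which `tofts_forward()` uses; the removable
singularity at $k_{ep} = m_i$ is replaced by its analytic limit
$t\,e^{-m_i t}$ whenever $|k_{ep} - m_i| < 10^{-8}$. The closed form is
verified against adaptive quadrature of the integral in the test suite.

**Units.** All kinetics are computed in minutes, and $K^{trans}$, $k_{ep}$
are reported in min⁻¹ (the units in which the AIF constants are defined);
multiply by $1/60$ for s⁻¹ if needed.

**Signal model.** Concentration is obtained from the signal by inverting
the spoiled gradient-echo steady state
$S = M_0 \sin\alpha\,(1-E)/(1-\cos\alpha\,E)$, $E = e^{-TR/T_1}$, with a
fixed precontrast $T_{1,0}$ of 820 ms (breast parenchyma) and the linear
fast-exchange relation $1/T_1(t) = 1/T_{1,0} + r_1 C(t)$. Defaults
(`signal_model_params()`): TR = 9.8 ms, flip angle 25°, and
$r_1 = 3.6$ L·mmol⁻¹·s⁻¹ for Gd-DOTA at 1.5 T — the relaxivity is an
external literature constant, exposed as a parameter. One pre-contrast
frame is assumed (`n_baseline = 1`): the bolus is injected at the start of
the first postcontrast scan of a 10-frame series with 56 s spacing.
Frames whose signal exceeds the SPGR saturation ceiling (non-invertible
$E \le 0$) are clipped to zero concentration and counted, never raised.

**Fitting.** `fit_tofts()` runs bounded Levenberg–Marquardt least squares
with bounds $K^{trans} \in [0, 5]$, $k_{ep} \in [0, 10]$ min⁻¹,
$v_p \in [0, 1]$, multi-started from the $\{low, mid\}$ grid per parameter
(8 starts); the lowest residual sum of squares wins, with convergence
tolerances of $10^{-10}$ on the relative reduction. On noiseless forward
curves the generating parameters are recovered to well under 0.1% median
relative error (tested at 500 voxels).

## Model-free TIC descriptors

Seventeen descriptors summarise each time-intensity curve. The curve is
split at its peak: wash-in runs from the first post-contrast frame through
the peak, wash-out from the peak to the last frame, and slopes/intercepts
(WIS, WII, WOS, WOI) are ordinary least-squares lines in signal units per
second. SB is the pre-contrast mean; MSD the peak enhancement; TTP the
frame time of the peak; AUC the trapezoidal area of $S(t) - SB$; AUCWI and
AUCWO the trapezoidal areas of the *concentration* curve over the
post-injection window split at the peak, so AUCWI + AUCWO is the total
post-injection area; HR $= (S_{last} - SB)/MSD$ measures persistence of
enhancement. Ratios with zero denominators are missing values by contract,
and a segment with fewer than two frames has slope 0 and intercept `NA`.

Three descriptors — the perfusion index (PI), sum of intensity differences
(SOD) and variance of enhancement slopes (VES) — are reconstructions: the
names are established in the semiquantitative-TIC literature but no single
formula is canonical, so this package defines them once and documents them
as its own reading: PI = AUC normalised by the observation interval,
SOD $= \sum_t (S(t) - SB)$, VES = variance of the successive
frame-to-frame enhancement slopes over the post-injection window. One
further ambiguity is resolved the same way: the area ratio is computed as
AUCWO/AUCWI (wash-out over wash-in), the direction that grows with
persistent enhancement.

## Diffusion: ADC and segmented IVIM

The monoexponential apparent diffusion coefficient is the log-linear
least-squares slope of $\ln S$ versus $b$ over all b-values
($ADC = \ln(S_0/S_b)/b$ in the two-point case). The intravoxel incoherent
motion model

$$S(b)/S_0 = f\,e^{-b D^*} + (1-f)\,e^{-b D}$$

is fitted in the standard segmented ("two-step") way, because the free
three-parameter fit is often ill-conditioned at seven b-values: first $D$
from a log-linear fit on $b > 200$ s/mm² (threshold exposed as a
parameter), where the pseudodiffusion term has decayed to $e^{-4}$-scale;
then $(f, D^*)$ by bounded nonlinear least squares of the full
biexponential over all b-values with $D$ held fixed and $S_0$ fixed at the
measured $b = 0$ signal (re-estimating $S_0$ in step 2 is a defensible
alternative; fixing it keeps the two steps strictly nested).
Initialisation: $f_0 = 1 - \text{intercept}/S_0$ from the high-b
extrapolation, $D^*_0 = 10 D$; bounds $f \in [0,1]$,
$D^* \in [D, 0.5]$ mm²/s. A fitted $D^* < D$ and a near-constant decay
(where $f$ is unidentifiable) are flagged, not raised. Recovery under 2%
magnitude noise is wide by design — median relative errors of roughly 2%
($D$), 14% ($f$) and 27% ($D^*$) at SNR 50 — reflecting the intrinsic
conditioning of the biexponential, not the optimiser.

## Coregistration

The two acquisitions live on different grids (defaults:
1.44 × 1.44 × 2 mm³ DCE, 1.52 × 1.52 × 6 mm³ DW). Analysis happens on a
common grid at 1.5 × 1.5 × 6 mm³ spanning only the intersection of the two
physical extents, so every analysed voxel is covered by both datasets. The
convention, used everywhere: world coordinates in mm at voxel centres,
`origin` the centre of voxel (1,1,1). Each frame is resampled by trilinear
interpolation — exact on linear fields, bounded by the source min/max
(convex weights), and refusing extrapolation outside the source extent.
Lesion masks are resampled by nearest neighbour, because fractional
membership would change ROI semantics.

## Classification

Voxel-level feature tables hold the 23 features (3 diffusion, 17 TIC, 3
kinetic); lesion-level tables take the per-lesion median of each feature.
`fit_lda()` is the two-class Fisher discriminant
$w \propto \Sigma_{pooled}^{-1}(\mu_{mal} - \mu_{ben})$ on internally
standardised features, with a ridge $\lambda = 10^{-6}\,\mathrm{tr}\,\Sigma$
added only when the pooled covariance is numerically singular (e.g.
duplicated features); weights are returned in original units, so the
discriminant is exactly affine-equivariant. The empirical ROC is computed
over all score thresholds and its AUC equals the normalised Mann–Whitney
statistic. The operating point maximises a prevalence-weighted Youden
index $J_w = w\,TPR - (1-w)\,FPR$ with $w$ defaulting to the empirical
malignant prevalence — one defensible operationalisation of choosing the
threshold "considering the class imbalance"; $w$ is a parameter. At voxel
level, lesions are then labelled by majority vote: malignant iff strictly
more than 50% of voxels are predicted malignant (a 50/50 tie is benign),
with the per-lesion percentage of correctly classified voxels reported.
No train/test split is performed by default (resubstitution), mirroring
the simple linear protocol the package models; the reported AUCs are
therefore optimistic for generalisation.

## The digital phantom

Because no patient data ship with the package, every stage is exercised on
a synthetic phantom with known ground truth. It emulates the acquisition
geometry above: 10 DCE frames at 56 s, b ∈ {0, 50, 100, 150, 400, 800,
1000} s/mm², 0.1 mL/kg dose, mismatched voxel grids with overlapping
extents, and a cohort of 16 benign + 15 malignant ellipsoidal lesions
placed without overlap on a jittered lattice. Matrix sizes (48 × 48 × 12
DCE, 46 × 46 × 4 DW) are deliberately smaller than a clinical acquisition
so a full cohort runs in about ten seconds; lesions are a few hundred mm³,
giving ~15–45 voxels each on the analysis grid.

Lesion parameters are drawn from class-conditional log-normal
distributions (`class_params()`), configuration data rather than code
constants. The defaults encode typical breast contrasts: benign medians
$K^{trans} = 0.08$, $k_{ep} = 0.45$ min⁻¹, $v_p = 0.02$, $f = 0.06$,
$D^* = 8\times10^{-3}$, $D = 1.6\times10^{-3}$ mm²/s; malignant medians
0.35, 1.3, 0.06, 0.12, $15\times10^{-3}$, $1.0\times10^{-3}$; between-lesion
`sdlog` 0.3 (0.15 for $D$) and within-lesion voxel heterogeneity `sdlog`
0.1. These values are the package's own choice, made once from the
quantitative-breast-MRI literature; no parameter ranges are canonical.
Noise is Rician (magnitude MRI) at a configurable fraction of the baseline
signal, with a Gaussian option for analytic tests; background tissue is
kinetically inert with constant baseline signal. Everything is
deterministic given `(config, seed)`.

What the phantom does *not* emulate: k-space sampling, coil sensitivity,
motion, fat suppression, partial-volume mixtures at lesion borders beyond
grid resampling, T2* effects, or patient-specific AIFs. Passing the
end-to-end tests therefore demonstrates that the estimators and the
classification machinery are correct and well-conditioned under the stated
noise model — not that the default effect sizes reproduce clinical
discrimination performance. With the default (well-separated) effect
sizes, the combined lesion-level classifier reaches AUC ≥ 0.9, and a
cohort generated with class-flat diffusion parameters shows the combined
classifier carried entirely by the DCE features; both are properties of
the configured generator, computed fresh by the test suite and the
acceptance script.

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(phantom_config(seed = 1), out_dir = "qmri_out")
print(run)
run$comparison_lesion$results$all$roc
head(run$lesion_table[, c("lesion_id", "label", "Ktrans", "kep", "f", "D")])
```

The run writes NIfTI volumes, CSV feature tables, a JSON classification
report and a manifest (seed, full configuration, per-stage counts)
sufficient to re-execute the run exactly.

## Interfaces

The package's functions are the primary interface; a thin command-line
wrapper over them ships in `inst/cli/breastqmri.R` with subcommands
`simulate`, `coregister`, `fit-dce`, `fit-dwi`, `classify` and `run`, each
a few lines over the exported functions. All intermediate artifacts are
plain files (NIfTI-1 with JSON sidecars, CSV, JSON), so any stage can be
re-run independently.

## Known limitations

- The AIF is a population curve; no patient-specific AIF or T1 mapping.
- Resubstitution classification only; the optional leave-one-lesion-out
  protocol common in larger studies is not implemented.
- PI, SOD and VES are this package's documented reconstructions of
  literature names without canonical formulas.
- The grid alignment assumes consistent world origins between modalities
  (true for the phantom; real data rely on scanner headers). No rigid or
  deformable registration is estimated.
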