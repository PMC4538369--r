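# breastqmri

Quantitative analysis of paired dynamic contrast-enhanced (DCE) and
diffusion-weighted (DW) breast MRI, for imaging scientists who want the
full chain from raw 4D series to a benign/malignant lesion classifier in
one tested, scriptable package:

- **Pharmacokinetics** — voxelwise extended Tofts fits
  `Ct(t) = Cp ⊗ Ktrans·e^(−kep·t) + vp·Cp` against the Weinmann
  population arterial input function, with signal↔concentration
  conversion through the spoiled gradient-echo equation at fixed
  precontrast T1.
- **Semiquantitative TIC analysis** — seventeen model-free descriptors of
  each time-intensity curve (basal signal, peak enhancement, time to
  peak, wash-in/wash-out slopes, intercepts and their ratios, areas under
  the signal and gadolinium curves, height ratio, perfusion index, sum of
  intensity differences, variance of enhancement slopes).
- **Diffusion** — monoexponential ADC and the segmented two-step IVIM fit
  `S(b)/S0 = f·e^(−b·D*) + (1−f)·e^(−b·D)`: D from the b > 200 s/mm²
  monoexponential regime, then (f, D*) by bounded nonlinear least squares
  with D fixed.
- **Coregistration** — both modalities trilinearly resampled onto a
  common 1.5 × 1.5 × 6 mm³ grid spanning only their shared physical
  extent; masks by nearest neighbour.
- **Classification** — Fisher linear discriminant on DCE-only, DW-only or
  all 23 features, empirical ROC with a prevalence-weighted Youden
  operating point, and a per-lesion majority vote over voxel predictions.
- **Digital phantom** — a seeded generator of paired DCE/DW volumes with
  ellipsoidal lesions, class-conditional log-normal tissue parameters and
  Rician noise, so the entire pipeline is testable with known ground
  truth.

## Worked example

```r
library(breastqmri)
run <- run_pipeline(phantom_config(seed = 1))
print(run)
```

```
breastqmri pipeline run
  31 lesions, 918 shared voxels on a 46 x 46 x 4 grid
Feature-set comparison (lesion level)
  dce  AUC = 1.000, TPR = 1.00, FPR = 0.00, misclassified lesions: 0
  dw   AUC = 1.000, TPR = 1.00, FPR = 0.00, misclassified lesions: 0
  all  AUC = 1.000, TPR = 1.00, FPR = 0.00, misclassified lesions: 0
Feature-set comparison (voxel level)
  dce  AUC = 1.000, TPR = 1.00, FPR = 0.00, misclassified lesions: 0
  dw   AUC = 0.781, TPR = 0.94, FPR = 0.36, misclassified lesions: 3
  all  AUC = 1.000, TPR = 1.00, FPR = 0.00, misclassified lesions: 0
```

The cohort is 16 benign and 15 malignant synthetic lesions with the
default class effect sizes, simulated, coregistered, fitted voxel by
voxel and classified at both levels. Lesion-level rows are per-lesion
medians:

```r
head(run$lesion_table[, c("lesion_id", "label", "n_voxels", "Ktrans", "kep", "f", "D")], 4)
```

```
  lesion_id     label n_voxels     Ktrans       kep          f            D
1         1 malignant       28 0.21250116 1.1866601 0.10817525 0.0009582184
2         2    benign       26 0.05151651 0.4707607 0.08653380 0.0013479800
3         3    benign       26 0.05562578 0.6196691 0.14546220 0.0012875583
4         4    benign       31 0.04334912 0.6565785 0.07575971 0.0014420969
```

Malignant lesions carry higher Ktrans/kep/f and lower D, as configured in
`class_params()`; Ktrans and kep are in min⁻¹, f dimensionless, D in
mm²/s. Single curves work the same way:

```r
t <- ((1:10) - 2) * 56 / 60            # 10 frames at 56 s, injection at frame 2
fit <- fit_tofts(tofts_forward(t, 0.25, 0.9, 0.04), t)
print(fit)
#> Extended Tofts fit
#>   Ktrans = 0.25 min^-1, kep = 0.9 min^-1, vp = 0.04
#>   RSS = 1.156e-32 over 10 frames, converged: TRUE
```

With `out_dir =`, `run_pipeline()` persists every stage as plain files
(NIfTI + JSON sidecars, CSV feature tables, a JSON classification report
and a run manifest with the seed and full configuration). A thin
command-line wrapper over the same functions ships in
`inst/cli/breastqmri.R` (`simulate`, `coregister`, `fit-dce`, `fit-dwi`,
`classify`, `run`).

See `vignettes/methods.Rmd` for the models, parameter defaults, numerical
choices and the phantom's scope.

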