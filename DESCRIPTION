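Package: breastqmri
Title: Multiparametric DCE-MRI and IVIM Analysis for Breast Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis pipeline for multiparametric breast MRI.
    Fits the extended Tofts pharmacokinetic model to dynamic contrast-enhanced
    (DCE) series against a biexponential Weinmann arterial input function,
    computes seventeen model-free time-intensity-curve descriptors, estimates
    ADC and intravoxel incoherent motion (IVIM) parameters from multi-b
    diffusion-weighted series by a segmented two-step fit, coregisters the two
    modalities onto a common grid by trilinear interpolation, and classifies
    lesions as benign or malignant with Fisher linear discriminant analysis,
    ROC analysis with an imbalance-aware operating point, and a per-lesion
    majority vote. Includes a digital phantom generator with known ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
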