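Package: alpscog
Title: Diffusion-Along-Perivascular-Space (ALPS) Imaging and Cognition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the DTI-ALPS index, a diffusion-tensor proxy for
    glymphatic (perivascular fluid transport) function, from diffusion-weighted
    MRI with automated ROI localization on directional-diffusivity profile
    curves, and links it to cognition in cohort studies of relapsing-remitting
    multiple sclerosis. Includes synthetic DWI phantoms with analytic
    ground-truth ALPS, lesion-mask and cohort simulators with planted effect
    structure, TIV-normalized volumetrics and lesion-burden features,
    healthy-control-referenced cognitive Z-scoring with BICAMS impairment
    classification, normality-gated group comparisons with effect sizes,
    Spearman screening with FDR control, covariate-adjusted linear models with
    VIF, backward stepwise logistic regression, and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    pROC,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
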