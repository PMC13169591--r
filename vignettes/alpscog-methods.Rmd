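---
title: "Methods: the DTI-ALPS index and its cohort-level analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS index and its cohort-level analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpscog)
```

## The scientific problem

The glymphatic system clears interstitial waste from the brain along
perivascular channels. It cannot be observed directly with clinical MRI, but
the **DTI-ALPS index** is a widely used proxy: at the level of the lateral
ventricle body, projection fibers run superior--inferior (z), association
fibers run anterior--posterior (y), and the deep medullary veins -- with
their perivascular spaces -- run left--right (x), perpendicular to both
fiber populations. If perivascular transport is active, water diffuses more
readily along x than the fiber geometry alone would allow. The index

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{proj}},\; D_{x,\mathrm{assoc}})}
                      {\mathrm{mean}(D_{y,\mathrm{proj}},\; D_{z,\mathrm{assoc}})}$$

is the ratio of perivascular-direction diffusivity to the diffusivity
perpendicular to both fiber tracts; values near 1 mean no preferential
perivascular diffusion, larger values mean more. $D_{z,\mathrm{proj}}$ and
$D_{y,\mathrm{assoc}}$ (the dominant fiber directions themselves) are carried
in results but deliberately excluded from the formula. In
relapsing--remitting multiple sclerosis (RRMS), periventricular inflammation
is thought to impair perivascular clearance, so a reduced ALPS index is a
candidate marker of cognitive risk. This package implements the full
quantitative chain from diffusion-weighted volumes to that claim: tensor
fitting, automated ROI placement, the index itself, structural covariates,
healthy-control-referenced cognitive Z-scores, and the association and
classification statistics that link them.

## Tensor fitting and scalar maps

Tensors are estimated per voxel by unweighted log-linear least squares on
$\ln S = \ln S_0 - b\, g^\top D g$, which is exact for noise-free data and
the standard default when no estimation method is otherwise specified.
Voxels with a non-positive $b_0$ signal are flagged invalid rather than
aborting a whole volume. A fitted tensor with a negative eigenvalue is
rebuilt from eigenvalues clamped to $10^{-7}$ mm$^2$/s and flagged, keeping
downstream ROI means defined while making the degeneracy visible.
Eigenvalues for the scalar maps (FA, MD, AD, RD) are computed by the
closed-form trigonometric solution for symmetric 3x3 matrices, vectorized
across all voxels; it is checked against dense eigendecomposition in the
test suite. FA of an all-zero tensor is defined as 0.

## Automated ROI localization

Real ALPS pipelines seed ROIs by registration to an FA template; this
package replaces that step by an explicit **search band** -- a set of
candidate (y, z) anchors supplied by the user (for phantoms, by the truth
manifest). For each anchor a circle of radius 5 mm (configurable) is swept
along x in the axial plane, and the mean tensor diagonal in the circle
yields three profile curves, the familiar red/green/blue color-map curves
(Dxx / Dyy / Dzz). Per hemisphere, the projection ROI is placed at the
highest blue-curve value and the association ROI at the highest green-curve
value across the whole candidate grid. A peak must exceed the hemisphere's
median curve level by a prominence factor (default 1.1), so a structureless
volume fails loudly instead of returning a meaningless index. Exact plateau
ties are resolved deterministically toward the band center. The two ROIs of
one hemisphere must not overlap; the midline defaults to the volume's
x-center.

The published ROI description, a "3 x 3x3 mm" sphere, is ambiguous; we read
it as a sphere of radius 1.5 mm in millimeter space. On a coarse clinical
grid (2.6 x 2.6 x 2.0 mm) such a sphere contains only the center voxel, so
the radius is an explicit, logged parameter and we recommend at least the
in-plane voxel size (2.6 mm, giving a 7-voxel sphere on that grid) whenever
single-voxel estimates would be noise-limited. The phantom studies in this
package use 2.6 mm for exactly that reason. Sphere membership is decided by
voxel-center distance in millimeters, so anisotropic voxels are handled
correctly.

## The synthetic phantom

`phantom_spec()` / `make_phantom()` build the geometry the ROI logic
assumes: an isotropic background (0.8e-3 mm$^2$/s), and per hemisphere one
projection block with $D = (1.2, 0.8, 1.6)\times 10^{-3}$ and one
association block with $D = (1.2, 1.6, 0.8)\times 10^{-3}$ mm$^2$/s,
mirror-symmetric about the midline, in a mid-axial band. The analytic truth
is ALPS $= \mathrm{mean}(1.2, 1.2)/\mathrm{mean}(0.8, 0.8) = 1.5$. Signals
follow the monoexponential tensor model at $b = 0$ and $1000$ s/mm$^2$ with
a fixed 64-direction table (a hemispheric Fibonacci-spiral set shipped as a
plain-text fixture; the acquisition's direction table is not public, so
this is a stand-in, not a reproduction). The default noise model is Rician
-- magnitude MRI -- with $\sigma = S_0/30$, i.e. a $b_0$ SNR of 30, a
typical clinical value; Gaussian and noise-free modes exist for analytic
checks. The grid is 64 x 64 x 32 voxels of 2.6 x 2.6 x 2.0 mm, the study's
DTI resolution; this size keeps a 10-seed Monte-Carlo recovery study under
two minutes on one CPU.

What the phantom does *not* emulate: real anatomy, partial-volume mixtures,
eddy/motion artifacts, multi-shell acquisitions. Passing recovery tests
shows the estimator chain is correct under its own geometric assumptions,
not that ROI placement is robust on arbitrary clinical data.

## The synthetic cohort

`effect_spec()` / `make_cohort()` generate a two-group table shaped like the
study cohort: 45 RRMS and 41 HC by default, with demographic and imaging
moments taken from the published group summaries under the SEM reading of
the "±" values (SD = SEM·sqrt(n); with the SD reading the published t
statistics are arithmetically impossible, with the SEM reading they
reproduce within rounding). Cognitive raw scores follow

$$\mathrm{raw} = \mu_{HC} + \sigma_{HC}\,\big(\beta_{age} z_{age} +
\beta_{sex}(sex - p) + \beta_{edu} z_{edu} + \beta_{ALPS} z_{ALPS} +
\beta_{nWMV} z_{nWMV} + \gamma\,[\mathrm{RRMS}] + \varepsilon\big)$$

with all coefficients on the standardized scale. ALPS and nWMV are
standardized by their own group's generative moments, and the default
residual SD completes each test's variance to unity, so a planted
coefficient *is* the standardized effect size an analysis of that group
should recover -- this is what makes parameter-recovery tests meaningful.
The default RRMS deficit $\gamma = -1.4$ SD matches the 1.3--2.2 SD gaps in
the published cognitive table and yields roughly half the simulated RRMS
group impaired under the BICAMS rule, as in the study. A separate latent
impairment outcome is drawn from a logistic model with log-odds $-1.2$ per
SD of ALPS and $-0.9$ per SD of nWMV (plus three independent null candidate
predictors), supporting selection-recovery studies of the stepwise model
that do not depend on the cognitive-score pathway. Sex is coded 0 = female,
1 = male everywhere.

## Z-scores, impairment, and the statistical chain

* **Normative models.** Each test is regressed on age, sex and education
  over HC rows; $Z = (\mathrm{raw} - \hat y)/\hat\sigma$ with
  $\hat\sigma$ the residual SD ($n-p$ denominator). The linear-additive form
  is a modelling choice (the functional form is not published). MMSE and
  MoCA go through the same procedure as every other test. A degenerate
  (zero) residual scale arises only in noiseless simulations; an exactly
  zero residual then maps to $Z = 0$, anything else is an error.
* **Impairment.** Impaired iff at least 2 of the 3 BICAMS domain Z-scores
  are $\le -1.5$; the boundary counts as impaired, and the rule is monotone.
* **Group comparisons.** Shapiro--Wilk at $\alpha = 0.05$ in both groups
  gates a pooled-variance t-test (Cohen's d, pooled SD, mean ± SEM
  descriptives) versus a Mann--Whitney U test (tie-corrected asymptotic Z
  without continuity correction, $r = |Z|/\sqrt{N}$, median/IQR
  descriptives); categorical variables use Pearson's chi-square. $N$ in $r$
  defaults to the full table size -- the convention that reproduces every
  published $r$, including the subgroup ones, and is therefore kept even
  though standardizing a subgroup Z by the full-study N is questionable.
* **FDR.** Benjamini--Hochberg within explicitly named families (one per
  reported table/screen); q-values always carry their family label.
* **Adjusted models.** OLS of each cognitive Z on screen-significant imaging
  predictors plus age/sex/education, with per-predictor B, 95% CI,
  standardized beta, VIF from auxiliary regressions, and BH q within the
  model.
* **Stepwise logistic.** Candidates are variables univariately significant
  between impaired and preserved; the full binomial GLM is pruned by
  repeatedly removing the largest Wald p while it exceeds 0.05 (criterion
  and threshold are modelling choices; the publication names neither).
  Separation is a hard error with a diagnostic. Retained terms report OR
  with Wald CIs, their single-predictor AUC (oriented $\ge 0.5$ with a
  direction flag, since protective markers discriminate "downward"), and
  the combined model its fitted-probability AUC.
* **AUC.** The tie-corrected rank statistic $U/(n_1 n_0)$, equal to the
  probability a random case outscores a random control with half credit for
  ties.

## Numerical and design choices worth knowing

* Profile/ROI geometry is computed in mm space throughout; voxel
  anisotropy (2.6 vs 2.0 mm) is never ignored.
* Peak ties: highest value wins; exact plateaus resolve toward the band
  center, then by index -- fully deterministic.
* The search band replaces MNI-template registration by design; on real
  data the user must supply a periventricular band, and the package makes
  no anatomical guess.
* Whether the study's reported ALPS is one hemisphere or the bilateral mean
  is not stated; this package reports left, right, and their arithmetic
  mean, and uses the bilateral mean as the headline value.
* Determinism: every stochastic generator takes an explicit seed and
  restores the caller's RNG state; identical spec + seed gives identical
  output.
* Problem sizes used by the shipped studies (10 phantom seeds at
  64 x 64 x 32; 50 cohort seeds at n = 200 RRMS; 100 null simulations;
  1,000 random FDR vectors) were chosen as the smallest sizes at which the
  Monte-Carlo bands in the acceptance checks are stable.

## Known limitations

The package deliberately excludes everything upstream of tensor estimation
(denoising, Gibbs-ringing, eddy/motion, bias-field correction), nonlinear
template registration and TBSS skeleton projection (the white-matter
diffusion summary is an FA > 0.2 mask mean instead -- a documented
divergence that preserves the quantity's role as a global WM summary, not a
reproduction of the skeleton values), lesion segmentation (masks are
inputs), and tissue segmentation / cortical thickness (consumed as
precomputed covariates). Cohort-level findings from the original study
(odds ratios, specific AUCs, Table 3 coefficients) are not reproducible
without the undeposited raw data; the synthetic cohort tests parameter
recovery, not the published point estimates.
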