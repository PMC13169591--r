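# alpscog

Glymphatic-proxy diffusion imaging and cognition in relapsing–remitting
multiple sclerosis (RRMS): an R package for computing the **DTI-ALPS index**
(diffusion along the perivascular space) from diffusion-tensor MRI with
automated ROI placement, deriving the structural covariates that accompany
it (TIV-normalized volumes, white-matter diffusion summaries, lesion
burden), converting cognitive raw scores to healthy-control-referenced
Z-scores with BICAMS impairment classification, and running the cohort
statistics that link imaging to cognition — normality-gated group
comparisons with effect sizes, Spearman screening with FDR control,
covariate-adjusted linear models with VIF, backward stepwise logistic
regression, and ROC analysis.

It is written for neuroimaging researchers who want the full quantitative
chain of an ALPS–cognition study as tested, reproducible code, and for
methodologists who want to study that chain's behavior on synthetic data
with known ground truth.

## The index

At the level of the lateral ventricle body, projection fibers run
superior–inferior (z), association fibers anterior–posterior (y), and the
perivascular spaces of the deep medullary veins left–right (x). With
per-ROI mean diffusivities `(Dx, Dy, Dz)` from a projection-fiber and an
association-fiber ROI per hemisphere,

```
ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
```

ALPS ≈ 1 means no preferential diffusion along the perivascular direction;
larger values indicate freer perivascular transport. The package locates
the four ROIs automatically at the peaks of directional-diffusivity profile
curves (the blue Dzz curve for projection, the green Dyy curve for
association) swept along x over a user-supplied periventricular search
band, and reports left, right, and bilateral (mean) indices with full ROI
and QC provenance.

## Worked example: phantom with known truth

A synthetic DWI phantom places mirror-symmetric projection and association
fiber blocks in an isotropic background, so the true index is analytic
(here 1.5), and simulates the two-shell, 64-direction acquisition with
Rician noise at b0 SNR 30:

```r
ph  <- make_phantom(phantom_spec(noise = "rician", seed = 1))
tv  <- fit_tensor(ph$dwi)
res <- subject_alps(tv, band = ph$truth$band, roi_radius = 2.6)
res
#> ALPS index (diffusion along the perivascular space)
#>   left  proj (Dx,Dy,Dz) = (1.2165, 0.8086, 1.6198) x1e-3; assoc = (1.2084, 1.6457, 0.7908) x1e-3; ALPS = 1.5161
#>   right proj (Dx,Dy,Dz) = (1.1598, 0.8090, 1.4996) x1e-3; assoc = (1.2341, 1.6371, 0.8112) x1e-3; ALPS = 1.4775
#>   bilateral ALPS = 1.4968
```

The bilateral estimate 1.4968 recovers the analytic truth 1.5 to 0.003
despite the noise; without noise the recovery is exact to machine
precision. Diffusivities are printed in 10^-3 mm^2/s.

## Worked example: synthetic cohort

`make_cohort()` draws an RRMS/HC cohort (default 45 + 41) with planted,
standardized ALPS effects on processing-speed and attention tests, and
`run_cohort()` executes the whole statistical pipeline:

```r
rep <- run_cohort(make_cohort(effect_spec(seed = 7)))
rep
#> Cohort report: 45 RRMS, 41 HC
#>   BICAMS impairment: impaired 26, preserved 19
#>   group differences (q < 0.05): alps, ngmv, fa, rd
#>   adjusted models fit for 9 outcome(s)
#>   stepwise retained: alps

rep$stepwise
#> Backward stepwise logistic regression (Wald, removal p > 0.05), n = 45
#>   removed: ncsfv (p=0.058)
#>   retained:
#>  term      B    OR ci_lo ci_hi     p   auc
#>  alps -3.489 0.031 0.002 0.526 0.016 0.692
#>   combined-model AUC = 0.692

rep$adjusted$z_sdmt
#> Adjusted linear model: z_sdmt ~ alps (+ age, sex, education), n = 45
#>  term     B ci_lo ci_hi beta_std     t p   vif q
#>  alps 2.456 1.481  3.43    0.654 5.094 0 1.152 0
```

Reading the output: about half the simulated RRMS group is classified
impaired under the BICAMS two-of-three Z ≤ −1.5 rule; the group comparison
flags the planted ALPS deficit; the adjusted model recovers a positive
standardized ALPS–SDMT association at unit-scale VIF; and the stepwise
model retains ALPS with an odds ratio below 1 — a higher index is
protective against impairment.

## Scope

Upstream image corrections (denoising, eddy/motion, bias field), template
registration, TBSS skeletonization, and lesion/tissue segmentation are out
of scope: lesion masks and volumetrics are inputs. See the methods vignette
(`vignettes/alpscog-methods.Rmd`) for the model, parameter defaults, design
decisions and limitations.
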