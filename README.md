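# dwialps

ALPS-index analysis of perivascular diffusivity from clinical
three-direction diffusion-weighted MRI, with a diffusion-tensor phantom
simulator and cohort-level statistics.

## The problem and who this is for

The glymphatic system clears brain waste along perivascular spaces. A
non-invasive proxy for its function is the **ALPS index**: at the axial
slice through the body of the lateral ventricle, the perivascular space
runs left-right (the image *x* axis), perpendicular to the cranio-caudal
projection fibers (*z*) lateral to the ventricle and to the
antero-posterior association fibers (*y*) further laterally. Preferential
water diffusivity along *x* in those two fiber regions — relative to the
fiber-perpendicular directions — indicates perivascular fluid mobility.

Full diffusion-tensor acquisitions are rarely part of routine imaging, but
three-direction DWI (one motion-probing gradient per image axis, b = 0 and
b = 1000 s/mm²) is ubiquitous. This package implements the DWI variant of
the index for researchers who want to compute it from such clinical
acquisitions and to study its behavior — e.g. its age trajectory — at
cohort level, plus a fully synthetic validation path so every stage can be
tested without patient data.

## The method

Per-axis apparent diffusion coefficients from the monoexponential decay
model, voxelwise:

    ADC_i = ln(S0 / S_i) / b ,   i ∈ {x, y, z}

A composite color image (x = red, y = green, z = blue) locates the
projection-fiber areas (blue-dominant) and association-fiber areas
(green-dominant) on the ventricle-body slice. Circular ROIs, mirrored left
and right, are measured on that slice and pooled bilaterally, giving

    ALPS index = mean(ADCx_proj, ADCx_assoc) / mean(ADCy_proj, ADCz_assoc)

An index near 1 means no preferential perivascular diffusivity. Cohort
statistics cover inter-observer agreement (Pearson r with Fisher-z CI, plus
ICC(2,1)), linear and quadratic age regressions, a strict over-40 subgroup
regression, and decade-wise one-way ANOVA with Tukey HSD post-hoc
comparisons.

The phantom simulator renders axis-aligned diffusion tensors into
b=0/b=1000 volumes with Rician noise and carries a closed-form ground-truth
index; the cohort simulator draws a quadratic age trajectory with subject
and observer noise. Both give every pipeline stage a known answer.

## Worked example

```r
library(dwialps)

## a noisy phantom at SNR 20 whose true index is 1.5
spec <- defaultPhantomSpec("realistic", sigma = 50)
ph   <- generatePhantom(spec, seed = 7)
measureSubject(ph$study, defaultRoiSet(), observerID = "A")
#> AlpsMeasurement subject 'phantom', observer 'A'
#>   ADCx(proj) 0.9093  ADCx(assoc) 0.9156  ADCy(proj) 0.6082  ADCz(assoc) 0.6181
#>   ALPS index: 1.4881

## a simulated 128-subject cohort with the default decade design
tab   <- generateCohort(defaultCohortSpec(), seed = 7)
stats <- cohortStatistics(tab)
stats$quadratic
#> RegressionResult (quadratic), n = 128
#>   coefficients: intercept = 1.31375, age = 0.0132391, age2 = -0.000151528
#>   R = 0.6063, vertex at 43.7 y
stats$interobserver$r
#> [1] 0.8531...
stats$anova
#> AnovaResult: F = 9.328, p = 3.424e-09 over 8 decade groups
#>   10 of 28 pairwise contrasts significant (Tukey, 0.05)
```

The measured index 1.4881 sits within 1% of the generating truth of 1.5
despite SNR-20 Rician noise; the four means are the bilaterally pooled ROI
diffusivities in 10⁻³ mm²/s. In the simulated cohort the fitted quadratic
peaks near the generative peak age of 45 years, and the decade ANOVA flags
the middle-aged groups against the extremes.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dwialps.R", package = "dwialps"))')" \
    run --out-dir out --seed 7
```

which simulates a phantom, writes ADC NIfTIs, the composite PNG, the
measurement CSV, cohort statistics JSON and a manifest.

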