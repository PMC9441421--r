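---
title: "Methods: the DWI ALPS index, its phantom, and its cohort statistics"
author: "dwialps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DWI ALPS index, its phantom, and its cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwialps)
```

## The measurement model

Three-direction diffusion-weighted imaging acquires a b = 0 volume and one
diffusion-weighted volume per motion-probing gradient, applied along each
image axis. Under monoexponential decay the per-axis apparent diffusion
coefficient is

$$ADC_i = \frac{\ln(S_0 / S_i)}{b}, \qquad i \in \{x, y, z\},$$

which this package reports in units of $10^{-3}\,\mathrm{mm^2/s}$. With
only two b-values per axis no tensor fit is possible; each axis is
inverted independently, which is exactly what the ALPS ratio needs. The
central assumption inherited from the acquisition is that the gradients
were applied along the *image* axes (orthogonal to the imaging plane), so
no gradient-to-image rotation is applied; `permuteAxes()` covers data
acquired with a different assignment. All voxel grids are 1-based
`[row, col, slice]` R arrays — the natural indexing of the language, used
consistently everywhere, including ROI centers.

At the axial slice through the body of the lateral ventricle the
perivascular space runs along $x$, perpendicular to the cranio-caudal
projection fibers ($z$-dominant diffusivity, imaged blue in the
$x{=}\mathrm{red}, y{=}\mathrm{green}, z{=}\mathrm{blue}$ composite) and to
the antero-posterior association fibers ($y$-dominant, green). The index

$$\mathrm{ALPS} =
  \frac{\operatorname{mean}(ADC_{x}^{proj},\ ADC_{x}^{assoc})}
       {\operatorname{mean}(ADC_{y}^{proj},\ ADC_{z}^{assoc})}$$

is therefore a ratio of perivascular-direction to fiber-perpendicular
diffusivity; 1 is the no-effect null, and the ratio is invariant to any
common rescaling of the four means.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bValue` | 1000 | s/mm² | the clinical DWI shell; any positive value is accepted |
| ROI radius | 3 | voxels | small enough to sit inside a fiber block, large enough (29 voxels) to average noise; configurable per region |
| `adcRef` (composite) | 2.0 | 10⁻³ mm²/s | normalization reference above typical parenchymal diffusivity, so tissue stays unsaturated while CSF clips to full brightness |
| CSF threshold (`suggestSlice`) | 2.0 | 10⁻³ mm²/s | mean-ADC level separating CSF from parenchyma |
| subgroup cutoff | 40 | years | strict (`age > 40`): "older than 40" excludes 40 itself |
| Tukey level | 0.05 | — | family-wise error for the all-pairs post-hoc comparisons |

Masking policy: a voxel with non-positive $S_0$ or any non-positive
diffusion-weighted signal carries `NA` in all three ADC maps (a clamp
would silently bias ROI means). Negative ADCs — noise pushing a
diffusion-weighted signal above $S_0$ — are retained and counted, because
zeroing them biases means upward; ROIs placed in white matter make them
rare. ROI membership uses the inclusive disc
$(r-c_r)^2 + (c-c_c)^2 \le \rho^2$, so voxel counts are bit-reproducible.
Left and right regions of each fiber type are averaged *before* the index
formula (a per-hemisphere option exists), treating the hemispheres
symmetrically.

## What the phantom emulates

`defaultPhantomSpec()` renders a 64×64×32 grid: an isotropic
CSF-like ventricle box ($D = 3.0$ everywhere, slices 13–21), mirrored
projection-fiber blocks adjacent-lateral to it, association-fiber blocks
further lateral, all in isotropic background ($D = 0.8$). Tensors are
specified by their diagonals only, principal axes aligned with the image
grid — a deliberate simplification, since the three-axis measurement is
blind to off-diagonal terms; real fibers are oblique and would shear
signal between axes in ways this phantom cannot represent. Noise is
Rician, $|s + n_1 + i n_2|$ with $n_1, n_2 \sim N(0, \sigma)$, applied
independently to all four volumes, because magnitude MRI noise (not
additive Gaussian) is what produces the small-signal upward bias that ADC
estimation must tolerate. With $S_0 = 1000$, $\sigma = 50$ gives SNR 20.

The default tensor preset (projection $D = (1.2, 0.4, 1.4)$, association
$D = (1.2, 1.4, 0.4)$) has the closed-form index
$(1.2{+}1.2)/(0.4{+}0.4) = 3.0$ — a deliberately sharp configuration whose
round-number truth makes end-to-end checks transparent. The `realistic`
preset (index 1.5) sits in the range reported for healthy adults, and the
`isotropic` preset (index 1.0) is the null. The ground-truth index depends
only on the tensors, never on grid, geometry or noise, which is what makes
it a usable oracle at every stage.

What passing phantom tests does **not** show: robustness to oblique fiber
orientations, partial-volume mixing at region boundaries, head-position
variation, eddy-current or susceptibility distortion — none of which the
phantom models. The phantom validates the arithmetic of the pipeline, not
the physiology of the measurement.

## The cohort generator and its calibration

`generateCohort()` draws integer ages uniformly within each decade using
the decade design 24/21/14/15/19/14/15/6 (n = 128, ages 10–89 — the decade
composition of the reference normal cohort), assigns the true index
$q(\mathrm{age}) = v_p - c\,(\mathrm{age} - a_p)^2$ plus
$N(0, \sigma_s^2)$ subject noise, and produces two observer readings by
adding independent $N(0, \sigma_o^2)$ noise. Defaults: peak age
$a_p = 45$ y, peak value $v_p = 1.6$, curvature $c = 1.2\times10^{-4}$
/y², $\sigma_s = 0.1$, $\sigma_o = 0.048$.

Calibration reasoning, fixed once: with $\sigma_s = 0.1$, curvature
$1.2\times10^{-4}$ makes the design-implied quadratic multiple correlation
($\approx 0.47$) and the over-40 subgroup linear correlation
($\approx -0.48$) bracket the moderate effect sizes observed in normal
cohorts; and the observer SD follows from the attenuation identity
$r = \sigma_T^2 / (\sigma_T^2 + \sigma_o^2)$ (where
$\sigma_T^2 = \operatorname{var}(q) + \sigma_s^2$ under the decade
design) solved for an expected inter-observer correlation of 0.85.
Ages are integers and decades are `floor(age/10)·10` buckets, matching how
such cohorts tabulate generations.

## Statistical procedures and numerical choices

* **Inter-observer agreement**: Pearson correlation (the conventional
  report), CI by Fisher z with $\mathrm{SE} = 1/\sqrt{n-3}$; ICC(2,1) is
  computed from the two-way mean squares as a clearly labeled extension.
* **Regressions**: ordinary least squares via `lm()`. The linear fit
  reports the signed $r$; a zero-variance response is reported as $r = 0$
  rather than `NA`. The quadratic fit reports
  $R = \sqrt{R^2}$ and, when concave, the vertex $-b_1/(2 b_2)$. Nesting
  guarantees $R \ge |r|$ on any data set (property-tested). Confidence
  bands are pointwise two-sided 95% `predict()` intervals over a 101-point
  age grid.
* **ANOVA**: one-way `aov()` across decades; all-pairs post-hoc by Tukey
  HSD at family-wise 0.05 — chosen because pairwise generation contrasts
  are the quantity of interest and Tukey is the standard symmetric
  all-pairs control. When the within-group sum of squares is exactly zero
  the limit ($F = \infty$, $p = 0$, unequal-mean pairs significant) is
  reported instead of QR round-off noise.
* **Boxplots**: type-7 (linear-interpolation) quantiles and the 1.5·IQR
  outlier rule, stated so that figures are reproducible to the number.
* **Ties and tie-breaks**: `suggestSlice()` returns the lowest slice index
  among equal-area CSF candidates; it is advisory only — the measured
  slice always comes from the `RoiSet`.
* **Determinism**: every stochastic stage takes one integer seed; the
  pipeline derives stage seeds by fixed offsets (phantom: `seed`, cohort:
  `seed + 1000`). CSV and JSON are written at full precision (`%.17g`,
  unrounded JSON), so identical seeds give byte-identical outputs.
* **PNG quantization**: channels are quantized round-half-up
  (`floor(255v + 0.5)`), making image files bit-stable.

## Problem sizes used in validation

The shipped validation suite works at sizes chosen to exercise every code
path while remaining quick on a laptop: the full 64×64×32 phantom for
exactness and determinism checks; 50 replicate SNR-20 phantoms for the
noise-robustness bound (mean index within 2% of truth); 100 replicate
cohorts (n = 128 each) for vertex recovery (mean within ±5 y of the
generative 45); and 1000 null cohorts for the ANOVA type-I calibration
(rejection rate in [0.03, 0.07] at $\alpha = 0.05$). The acceptance script
`scripts/acceptance.R` re-runs all of these from a single seed.

## Known limitations

* Three axis-aligned gradients cannot measure off-diagonal tensor terms;
  oblique fibers alias into the axis diffusivities, and the phantom shares
  this blindness by construction.
* ROIs are config-driven geometric circles, a reproducible stand-in for
  expert anatomical placement; no atlas registration is attempted.
* The composite rendering is a diffusivity-scaled color map, not true
  eigenvector color-FA (which does not exist for this acquisition); it is
  sufficient for locating the two fiber areas, not for tractography-grade
  orientation mapping.
* The cohort generator models a clean quadratic trajectory with Gaussian
  noise; real cohorts carry indication bias, heteroscedastic ages, and
  observer effects correlated across subjects, none of which are
  simulated.
* In-plane resolution and slice thickness of the source DWI are not part
  of the model; phantom voxel spacing defaults to 1 mm isotropic and is
  configurable but untested against anisotropic voxels.
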