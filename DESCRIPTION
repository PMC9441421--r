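Package: dwialps
Title: ALPS Index of Perivascular Diffusivity from Three-Direction
    Diffusion-Weighted MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the ALPS (analysis along the perivascular space) index
    from clinical three-direction diffusion-weighted MRI. Provides per-axis
    apparent diffusion coefficient (ADC) mapping from b=0 and
    diffusion-weighted volumes, directional red-green-blue composite images
    for locating the projection- and association-fiber measurement regions,
    circular region-of-interest measurement with bilateral pooling, and the
    ALPS ratio itself. Cohort-level statistics cover inter-observer
    correlation, linear and quadratic age regressions, a subgroup regression,
    and decade-wise analysis of variance with Tukey post-hoc comparisons. A
    diffusion-tensor phantom simulator with Rician noise and closed-form
    ground-truth indices, plus a cohort simulator with a quadratic age
    trajectory, support end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    RNifti,
    yaml,
    jsonlite,
    png,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'core_model.R'
    'nifti_io.R'
    'adc_maps.R'
    'composite.R'
    'measurement.R'
    'cohort_stats.R'
    'phantom.R'
    'cohort_sim.R'
    'pipeline.R'
    'cli.R'
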