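Package: ppmap
Type: Package
Title: Posterior-Pole Structure-Function Mapping for Optic Neuropathy Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds the 7-degree-rotated 64-point posterior-pole fundus
    perimetry test pattern and co-registers point sensitivities with 8x8
    spectral-domain OCT layer-thickness grids to form combined
    morpho-functional maps. Ships a calibrated synthetic cohort generator
    for autosomal dominant optic atrophy (ADOA) and control eyes, group and
    pointwise comparisons (one-way ANOVA with Bonferroni correction),
    Pearson and partial correlations, fixation stability via the bivariate
    contour ellipse area (BCEA), Monte-Carlo power, and ROC analysis with a
    Youden-optimal ganglion-cell-layer thickness cutoff for absolute
    scotomas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    MASS,
    pracma,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
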