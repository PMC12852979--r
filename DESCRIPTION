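Package: ligamentCECT
Title: Contrast-Enhanced Micro-CT and Viscoelastic Analysis of Ligament
    Microdamage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting ligament microdamage by combining
    tensile viscoelastic testing with contrast-enhanced micro computed
    tomography (CECT). Extracts Young's modulus, two-exponential (Prony)
    stress-relaxation parameters, sinusoidal phase shift, yield point and
    damage parameters from mechanical test traces; calibrates micro-CT volumes
    to Hounsfield units, segments tissue and fascicle/interfascicular-matrix
    structure by k-means clustering, and fits first-order exponential
    contrast-agent uptake (equilibrium partition Pmax and diffusion time
    constant tau). Paired Wilcoxon signed-rank comparisons and Spearman
    correlation screening link biomechanics to CECT. A synthetic-data module
    generates mechanical traces, diffusion series, 3D CT phantoms and paired
    cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    tiff,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
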