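Package: octamorph
Title: Retinal OCTA Capillary-Plexus Quantification and Adaptive-Optics
    Arteriolar Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the superficial capillary plexus of en-face optical
    coherence tomography angiography (OCTA) images: foveal avascular zone
    (FAZ) morphometry (area, perimeter, circularity), multiscale Hessian
    (Frangi) vessel enhancement, Phansalkar local thresholding, vessel
    density, skeleton-based vessel length density and box-counting fractal
    dimension, all inside a FAZ-centred 3 mm analysis disc with
    Littmann-Bennett axial-length correction.  Derives arteriolar wall
    metrics (wall thickness, wall-to-lumen ratio, wall cross-sectional
    area) from adaptive-optics diameter measurements, and provides the
    cohort-level statistical stage (Shapiro-Wilk gated ANOVA or
    Kruskal-Wallis with Tukey or Dunn post hoc comparisons, Spearman
    correlation).  Includes seeded generators for synthetic vascular
    phantoms with ground truth and synthetic per-eye cohorts for testing
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
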