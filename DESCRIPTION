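Package: uamorph
Title: Three-Dimensional Upper-Airway Morphometry for Jaw-Displacement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated three-dimensional analysis of the morphological
    response of the pharyngeal airway to maxillo-mandibular surgical
    displacement. Provides watertight triangular-mesh handling (STL input and
    output, volume, surface-distance maps), landmark-based rigid registration
    with iterative-closest-point refinement and signed six-degree-of-freedom
    bone-displacement extraction, partition of the airway into 25 region-labelled
    slabs with projected cross-sectional areas and volume deltas, and the
    threshold statistics used to locate the antero-posterior displacement
    threshold (ANOVA, Games-Howell, Mann-Whitney, ROC curves with Youden-index
    cut-point and dual-peak detection, combined-displacement logistic ROC).
    A synthetic cohort generator produces paired pre- and post-operative airway
    meshes and landmark sets with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
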