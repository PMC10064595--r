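Package: cryomargin
Title: Volumetric Ablation Margin Analysis for Image-Guided Cryoablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies three-dimensional ablation margins between a tumor
    segmentation and the ice-ball segmentation from image-guided percutaneous
    cryoablation. Computes the signed minimal treatment margin (MTM) from an
    anisotropic Euclidean distance transform on co-registered binary masks,
    localizes it by anatomical octant, classifies tumor coverage relative to a
    user-defined margin threshold, and derives tumor and ice-ball morphometry
    (volume, maximum 3D diameter). Includes landmark-based rigid
    co-registration, exact contingency-table tests (Fisher and
    Freeman-Halton), Cox proportional-hazards and Kaplan-Meier analysis of
    local tumor progression, and synthetic phantom and cohort generators with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    survival,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
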