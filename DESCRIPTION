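Package: mkunet
Title: Medical-Knowledge-Fused 3D U-Net for Longitudinal Lung CT Tumor
    Segmentation and Immune-Evasion Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal lung-CT tumor analysis: multi-modal
    preprocessing of CT volumes (Hounsfield-unit passthrough, Canny edge
    maps, 3D Gaussian denoising, windowed gray-level co-occurrence
    contrast, adaptive intensity windowing), tumor growth kinetics via the
    log volume change rate (LVCR, a weighted least-squares slope of log
    tumor volume on time), a 3D encoder-decoder segmentation network with
    attention-gated skip connections, clinical-metadata fusion at the
    bottleneck and LVCR-conditioned immune-aware attention gates, a hybrid
    Dice + binary cross-entropy training objective, segmentation metrics
    (Dice, IoU, 95th-percentile Hausdorff distance) with LVCR-stratified
    reporting, shape radiomics (mesh-based sphericity), and a composite
    Immune Evasion Score. A synthetic longitudinal CT phantom generator
    with known ground truth makes every component testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
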