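Package: vascumet
Title: Concurrent Tumor Metabolism and Vascular Morphometry from Dynamic
    PET and Ultrafast Doppler
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for concurrent quantification of tumor
    glucose metabolism and vascular architecture on a shared voxel grid.
    Implements dynamic FDG-PET kinetic analysis (SUV, image-derived input
    function, irreversible two-tissue-compartment fitting, Patlak
    linearization, MRGlu, total lesion glycolysis), SVD clutter filtering
    and power-Doppler integration of ultrafast ultrasound frame stacks,
    blind kernel estimation with Richardson-Lucy deconvolution,
    Hessian-based vessel enhancement, isodata thresholding, 3D
    skeletonization and vessel-graph morphometry, SUV-band regional vessel
    density, immunofluorescence field quantification, and longitudinal
    cohort statistics. Ships a synthetic-phantom generator with known
    ground truth so that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
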