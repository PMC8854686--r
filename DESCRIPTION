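Package: trackcells
Title: Cell Tracking by Detection with Lineage Editing and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless toolkit for tracking cells in 2D time-lapse
    fluorescence microscopy. Provides Laplacian-of-Gaussian spot detection
    with marker-controlled watershed region formation and a plugin hook for
    external detectors; two-stage linear-assignment-problem (LAP) linking
    that chains per-frame detections into track segments and then closes
    gaps and resolves cell divisions into a lineage; particle-filter
    sequential tracking of single targets with checkpoint/correct/resume
    semantics; a programmatic trajectory-editing API with a replayable edit
    script format; the Cell Tracking Challenge evaluation metrics
    (SEG/DET/TRA via AOGM graph-edit costs); a synthetic movie generator
    with exact ground-truth masks and lineages; and readers/writers for
    multi-page TIFF stacks, Cell Tracking Challenge result directories and
    CSV tables, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
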