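Package: gmnet
Title: Single-Subject Grey Matter Network Construction and Small-World Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs single-subject grey matter similarity networks from
    segmented T1 partial-volume maps (3x3x3-voxel cube nodes,
    rotation-maximized correlation edges, FDR-thresholded binarization),
    quantifies small-worldness (sigma, gamma, lambda) against
    degree-preserving random reference ensembles at whole-brain and
    atlas-masked regional scales, and runs the accompanying group-comparison
    and anhedonia-correlation statistics (Welch t, Yates chi-square, ANCOVA,
    partial correlation, Fisher r-to-z, Benjamini-Hochberg FDR). Includes a
    synthetic cohort generator that emulates a two-group structural MRI study
    with controllable network regularity and scale coupling, so the whole
    pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
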