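Package: synscreen
Title: Probabilistic Punctum and Synapse Detection for Synaptic Antibody
    Screening in Array Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects immunofluorescence puncta in aligned serial-section
    (array tomography) image volumes with a probabilistic, query-based
    detector: a Gaussian background model turns raw intensities into
    foreground probabilities, window products enforce a minimum in-plane
    blob size, and consecutive-slice products enforce a minimum section
    span.  Candidate-antibody puncta are then associated with reference
    antibody puncta (colocalized or adjacent) to detect target synapses,
    and per-antibody performance measures are derived: punctum density,
    punctum volume statistics, target synapse density and the target
    specificity ratio.  Includes a ground-truthed synthetic-volume
    generator for validation, multi-page TIFF I/O, query-sweep and
    screening/ranking utilities, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
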