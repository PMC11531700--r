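Package: swWavefront
Title: Wavefront Lane-Group Smith-Waterman Protein Database Search
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Score-only Smith-Waterman local alignment with affine gap
    penalties, computed by a deterministic emulation of a lane-group
    wavefront engine: p lockstep lanes each owning k dynamic-programming
    columns, shuffle-style boundary exchange between lanes, query-character
    rotation registers, column-chunk tiling for long subjects, and
    16-bit/half-precision arithmetic modes with overflow flagging and
    wide-integer recompute. Includes a makeDB-style FASTA preprocessor
    producing a length-sorted binary database, length-binned batched
    scanning with top-k ranking and multi-worker partitioning, an analytic
    peak-performance model (cell updates per second) for GPU-class
    architectures, and seeded synthetic database generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
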