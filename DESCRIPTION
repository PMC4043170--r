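Package: clonewave
Title: Clonal Waves, Reproductive Capacity and Mutation Diversity in
    Hierarchically Organized Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multi-compartment model of cells carrying multiple
    neutral mutations in a hierarchically organized tissue such as the
    haematopoietic system. Provides closed-form solutions for the expected
    clonal wave travelling through the differentiation hierarchy, the
    reproductive capacity of a single founder cell, the expected number of
    distinct mutations founded within its clonal progeny, and a matching
    exact (Gillespie) individual-based stochastic simulator with full
    lineage tracking. Includes the childhood acute lymphoblastic leukaemia
    case-study pipeline: inversion of the differentiation probability from
    tumour burden, time-to-load estimates, and predicted clonal diversity
    ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
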