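Package: acdscan
Title: Iterative Profile-HMM Detection and Architecture Annotation of
    Small Heat Shock Proteins
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects small heat shock proteins (sHSPs) and delineates
    their Alpha Crystallin Domain (ACD) with a structure-seeded,
    iteratively enriched profile hidden Markov model.  A seed multiple
    alignment annotated with beta-strand landmarks is compiled into a
    glocal profile HMM, scores are converted to E-values through Gumbel
    calibration on random sequences, and a databank is scanned and
    re-scanned while the acceptance threshold is relaxed one order of
    magnitude per iteration.  Detected monomers are sliced into
    N-terminal region, ACD zones (beta2-beta5, L57 loop, beta7-beta9),
    the C-terminal Anchoring Module (CAM) ending at the I/V/L-X-I/V/L
    motif, and the C-terminal tail.  Group-level statistics, bacterial
    class A/B assignment by global alignment, gap-aware sequence logos
    and a fully synthetic benchmark generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    S4Vectors,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
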