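Package: dtinet
Title: Gene-Regulatory Network Inference from Time Courses via Directed
    Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed transcription-factor to gene regulatory
    interactions from replicated, equidistant expression time courses.
    Directed information between gene pairs is estimated with B-spline or
    kernel-density mutual-information estimators, converted to cumulative
    z-scores by the context-likelihood-of-relatedness (CLR) background
    correction restricted to the TF-by-gene matrix, and thresholded at a
    target precision against a reference interaction network. Inferred
    edges can be validated at the sequence level by scanning promoter
    regions with a position weight matrix built from known binding sites
    and requiring overlap with phylogenetically conserved intervals, with
    optional expansion of accepted edges across operons. A synthetic-data
    generator produces ground-truth networks, time courses, promoters
    with planted binding sites, and recovery metrics for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
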