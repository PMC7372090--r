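Package: alfpipe
Title: Characterization of Unknown Transgene Insertion Events from
    Enrichment-Anchored Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing unknown genetically modified (GM)
    plant events from targeted-enrichment long-read sequencing. Implements
    a simulator for ALF-enriched (amplification of linearly-enriched
    fragments) nanopore-style reads anchored at an element primer and
    spanning a construct-genome junction; the read selection cascade
    (quality control, primer selection, two-stage known-sequence
    subtraction), greedy read clustering, consensus building, consensus
    annotation against an element database, and junction calling; in
    silico PCR verification of event-specific primer/probe assays with
    cross-event specificity matrices; real-time PCR validation arithmetic
    (genome copies from DNA mass, calibration-curve fit, amplification
    efficiency, limit of detection); and a rule-based decision support
    system assigning screening-PCR result panels to GM groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
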