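Package: estqc
Title: EST-Based Evaluation of Genome Assembly Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the quality of genome assemblies with expressed
    sequence tags (ESTs). Implements stratified two-round random EST
    sampling, vector/adaptor clipping and contaminant screening,
    an est2genome-style spliced EST-to-genome aligner with k-mer seeding,
    per-0.1-Mb segment coverage profiling, GC-content and three-class
    repeat profiling, and a four-level assembly quality classification
    from integrity (assembled size over genome size), accuracy (matched
    over selected ESTs) and segment-matching proportion. Ships a
    synthetic-data generator (genomes with planted genes, repeats, N
    gaps and assembly defects; EST libraries with sequencing error,
    vector flanks and organelle/rRNA/bacterial contaminants) with a
    full truth ledger so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
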