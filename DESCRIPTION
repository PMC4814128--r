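Package: dmgfinder
Title: Diagnostic Marker Gene Prediction for Bacterial Strain Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Group-versus-group comparative genomics for the prediction of
    diagnostic marker genes (DMGs): genes present in (nearly) all genomes of
    a phenotype-defined target group and absent from all background genomes.
    Implements a six-step filtering pipeline over annotated open reading
    frames and whole-genome contigs using a built-in seed-and-extend local
    alignment engine (with an optional external BLAST+ backend), an
    annotation equalizer that repairs inconsistent gene calling within a
    group, alternative discontiguous/protein/mutation-level search modes, a
    distribution mode producing gene-by-strain presence and copy-number
    matrices, marker validation statistics (two-sided Fisher exact test,
    Spearman rank correlation, confusion counts), and a deterministic
    synthetic-data generator with a ground-truth manifest for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'utils.R'
    'classes.R'
    'align.R'
    'dmgfinder-package.R'
    'pipeline.R'
    'equalizer.R'
    'outputs.R'
    'seq-io.R'
    'synthgen.R'
    'validation.R'
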