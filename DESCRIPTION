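Package: cloverleaf
Title: Profile-SCFG Detection and Classification of tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact profile stochastic context-free grammars (covariance
    models) from structure-annotated tRNA seed alignments and uses them to detect
    and classify tRNA genes in nucleotide sequences. Implements a two-pass genome
    scanner (structure-free first pass, structural CYK second pass), comparative
    isotype classification against suites of isotype-specific models, detection of
    canonical and noncanonical bulge-helix-bulge introns by iterative splicing and
    rescoring, pseudogene and high-confidence filtering of predictions, a
    vertebrate mitochondrial search mode, fifth-order Markov virtual genomes for
    false-positive calibration, and categorized comparison of annotation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
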