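Package: dualguide
Title: Editing-Outcome Analysis for Dual-Guide CRISPR Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing amplicon deep-sequencing experiments in which
    a gene is targeted by two CRISPR/Cas9 single guide RNAs at once. Models the
    reference amplicon geometry (protospacers, PAMs, blunt cut sites and the
    inter-cut segment), constructs edited alleles (small indels, inter-cut
    large deletions, inter-cut inversions, substitutions), simulates paired-end
    amplicon reads from allele mixtures, merges and classifies every read by a
    template-competition aligner and by a flank-anchored split mode that
    recovers large deletions (splice-junction-style gaps) and inversions
    (soft-clip logic), summarises per-sample editing status and chimerism,
    predicts diagnostic PCR products and gel profiles, and reproduces
    transformation-efficiency arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
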