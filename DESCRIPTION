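Package: cloneseq
Title: Pooled Site-Directed Mutagenesis Verification and Comparative
    Interactome Scanning
Version: 0.1.0
Authors@R:
    person("Clone-seq", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for massively parallel site-directed
    mutagenesis verified by pooled next-generation sequencing
    ("Clone-seq"), and for downstream comparative interactome scanning.
    Includes QuikChange-style mutagenesis primer design, a synthetic
    pooled-colony read simulator with known ground truth, a minimal
    ungapped read mapper and samtools-mpileup-dialect reader producing
    per-position allele counts, S-score based calling of successful
    mutagenesis attempts with binomial detection of unwanted PCR
    mutations, GFP plate-reader stability calls, yeast two-hybrid
    disruption scoring, solvent-accessible surface area interface
    classification of mutation loci, SILAC differential-interaction
    scoring, and cohort-level concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
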