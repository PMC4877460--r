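Package: miRtrend
Title: IsomiR-Aware Small RNA Quantification and Gradient Differential
    Expression Across Tissue States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small RNA sequencing studies that compare miRNA
    expression across ordered tissue states (normal, tumor-adjacent,
    tumor). Reads are matched to precursor hairpins with isomiR-aware
    rules (mature region plus or minus 4 nt, at most one mismatch),
    counts are normalized to counts per million, differential expression
    between two libraries is tested with the Audic-Claverie exact test
    under Poisson sampling with Benjamini-Hochberg FDR control and
    fold-change gating, and miRNAs changing monotonically across the
    three states are called as expression gradients. Companion modules
    provide delta-delta-Ct qPCR quantification against a reference gene,
    a base-pair-maximization hairpin plausibility check for candidate
    precursors, hypergeometric over-representation analysis against
    user-supplied gene sets, and a fully seeded synthetic-data generator
    (precursors, reads, count matrices, qPCR plates) with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    fgsea,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
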