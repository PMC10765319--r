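Package: pimtkd
Title: Paired Bulk and Downsampling-Balanced Single-Cell Differential
    Expression for PIM Triple-Knockdown Th17 Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptomic readouts of simultaneous
    PIM1/PIM2/PIM3 silencing (triple knockdown, TKD) in differentiating
    Th17 cells.  Provides paired bulk RNA-seq differential expression with
    trimmed-mean-of-M-values (TMM) normalization and a paired
    reproducibility-optimized resampling test with permutation FDR;
    single-cell QC, depth log-normalization, knockdown-negative (PIM-)
    cell classification, and a downsampling-balanced Wilcoxon rank-sum
    differential expression procedure aggregated as the proportion of
    subsets in which a gene qualifies (signif_prop); cross-modality
    gene-set concordance; ddCt qPCR quantification and live-cell
    normalized assay readouts.  A negative-binomial synthetic-data
    generator with planted effects and knockdown-silenced cells makes
    every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
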