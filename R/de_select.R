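# Threshold selection on a bulk DE table, row standardization for
# heatmaps, and the same-direction intersection across timepoints.

#' Select differentially expressed genes by FDR and fold change
#'
#' Both inequalities are strict: FDR strictly below `fdr_max` ("below
#' 0.1") and linear fold change strictly above `fc_min` ("above 1.4"),
#' with FC read two-sided as `2^|mean log2FC|`. The relaxed exploratory
#' tier uses `fdr_max = 0.25`.
#'
#' @param table a `bulk_de_table` from [paired_rots_test()].
#' @param fdr_max FDR cutoff (default 0.1).
#' @param fc_min linear fold-change cutoff (default 1.4).
#' @return a [signed_gene_set()] tagged with the table's timepoint.
#' @export
select_de <- function(table, fdr_max = 0.1, fc_min = 1.4) {
  stopifnot(is.data.frame(table),
            all(c("gene", "fdr", "fc", "direction") %in% names(table)))
  keep <- table$fdr < fdr_max & table$fc > fc_min
  signed_gene_set(table$gene[keep], table$direction[keep],
                  provenance = paste0("bulk_", attr(table, "timepoint")))
}

#' Row-standardize an expression matrix to z-scores
#'
#' Each selected gene's row is centered and scaled to mean 0, sd 1
#' (denominator n-1), the form used for expression heatmaps.
#'
#' @param expr gene x sample numeric matrix (e.g. log2 cpm).
#' @param genes genes (row names) to standardize; default all rows.
#' @return matrix of the selected rows, standardized.
#' @export
zscore_matrix <- function(expr, genes = rownames(expr)) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) halt("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    halt("zero-variance gene(s): %s", paste(genes[sds == 0], collapse = ", "))
  t(scale(t(x)))[, , drop = FALSE]
}

#' Genes shared between two signed sets with matching direction
#'
#' The timepoint-concordance operation: the intersection of the 6 h and
#' 24 h selections restricted to genes regulated in the same direction.
#'
#' @param set_a,set_b [signed_gene_set()]s.
#' @return a [signed_gene_set()] of the same-direction intersection.
#' @export
common_direction_genes <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "signed_gene_set"), inherits(set_b, "signed_gene_set"))
  common <- intersect(set_a$gene, set_b$gene)
  da <- set_a$direction[match(common, set_a$gene)]
  db <- set_b$direction[match(common, set_b$gene)]
  same <- common[da == db]
  signed_gene_set(same, da[da == db],
                  provenance = paste(attr(set_a, "provenance"),
                                     attr(set_b, "provenance"), sep = "&"))
}
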