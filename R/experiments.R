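# Containers for the two assay modalities.
#
# BulkExperiment: dense gene x sample integer counts with a paired-design
# sample table (condition TKD/Scr, donor pair, timepoint).
# SCExperiment: sparse gene x cell counts with a feature table carrying the
# mitochondrial flag and a per-cell sample label.

#' Construct a bulk RNA-seq experiment
#'
#' Bundles a gene x sample count matrix with its paired-design metadata.
#' Each donor pair must contribute exactly one TKD and one Scr sample per
#' timepoint; this is what makes paired testing well defined.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param samples data.frame with columns `sample`, `condition`
#'   (`"Scr"`/`"TKD"`), `pair`, `timepoint`; one row per column of `counts`,
#'   matched by the `sample` column.
#' @return an object of class `BulkExperiment` (list with `counts`,
#'   `samples`).
#' @export
bulk_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) halt("counts must have gene rownames")
  if (is.null(colnames(counts))) halt("counts must have sample colnames")
  if (any(counts < 0) || any(counts != floor(counts)))
    halt("counts must be non-negative integers")
  req <- c("sample", "condition", "pair", "timepoint")
  miss <- setdiff(req, names(samples))
  if (length(miss)) halt("samples metadata lacks column(s): %s", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(counts))
    halt("metadata rows (%d) != count columns (%d)", nrow(samples), ncol(counts))
  if (!setequal(samples$sample, colnames(counts)))
    halt("sample names in metadata and count columns disagree")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$condition %in% c("Scr", "TKD")))
    halt("condition must be 'Scr' or 'TKD'")
  # each pair once per condition within a timepoint
  key <- paste(samples$timepoint, samples$condition, samples$pair)
  if (anyDuplicated(key))
    halt("duplicated (timepoint, condition, pair) combination in metadata")
  structure(list(counts = counts, samples = samples), class = "BulkExperiment")
}

#' @export
print.BulkExperiment <- function(x, ...) {
  cat(sprintf("BulkExperiment: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  timepoints: %s; pairs: %s\n",
              paste(unique(x$samples$timepoint), collapse = ", "),
              paste(unique(x$samples$pair), collapse = ", ")))
  invisible(x)
}

#' @export
dim.BulkExperiment <- function(x) dim(x$counts)

#' Construct a single-cell experiment
#'
#' @param counts gene x cell count matrix (dense or sparse; stored as
#'   `dgCMatrix`). Rownames are gene ids, colnames are cell barcodes.
#' @param features data.frame with `gene_id`, `gene_name` (one row per count
#'   row). A logical `is_mito` column may be supplied; if absent it is
#'   derived from the `"MT-"` prefix of `gene_name`.
#' @param sample_of character/factor of per-cell sample labels
#'   (e.g. `"Scr"`, `"TKD"`), one per column.
#' @param mito_genes optional explicit character vector of mitochondrial
#'   gene names, overriding the prefix rule.
#' @return an object of class `SCExperiment` (list with `counts`, `features`,
#'   `barcodes`, `sample_of`).
#' @export
sc_experiment <- function(counts, features, sample_of, mito_genes = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != floor(counts@x)))
    halt("counts must be non-negative integers")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "gene_name") %in% names(features)))
    halt("features must have gene_id and gene_name columns")
  if (nrow(features) != nrow(counts))
    halt("feature rows (%d) != count rows (%d)", nrow(features), nrow(counts))
  if (is.null(rownames(counts))) rownames(counts) <- features$gene_id
  if (is.null(colnames(counts))) halt("counts must have cell barcodes as colnames")
  if (length(sample_of) != ncol(counts))
    halt("sample_of length (%d) != number of cells (%d)", length(sample_of), ncol(counts))
  if (!is.null(mito_genes)) {
    features$is_mito <- features$gene_name %in% mito_genes
  } else if (is.null(features$is_mito)) {
    features$is_mito <- startsWith(features$gene_name, "MT-")
  }
  if (anyDuplicated(colnames(counts)))
    halt("duplicated cell barcodes; disambiguate with a sample suffix")
  structure(list(counts = counts,
                 features = features,
                 barcodes = colnames(counts),
                 sample_of = as.character(sample_of)),
            class = "SCExperiment")
}

#' @export
print.SCExperiment <- function(x, ...) {
  tab <- table(x$sample_of)
  cat(sprintf("SCExperiment: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.SCExperiment <- function(x) dim(x$counts)

#' A gene set with per-gene direction
#'
#' The common currency of threshold selection and cross-modality overlap:
#' a set of genes each tagged `"up"` or `"down"`.
#'
#' @param genes character vector of unique gene ids.
#' @param direction character vector, `"up"`/`"down"`, recycled if length 1.
#' @param provenance label recording which analysis produced the set
#'   (e.g. `"bulk_6h"`, `"sc"`).
#' @return data.frame of class `signed_gene_set` with columns `gene`,
#'   `direction` and a `provenance` attribute.
#' @export
signed_gene_set <- function(genes, direction, provenance = NA_character_) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) halt("genes in a signed set must be unique")
  direction <- rep_len(as.character(direction), length(genes))
  if (length(genes) && !all(direction %in% c("up", "down")))
    halt("direction must be 'up' or 'down'")
  structure(data.frame(gene = genes, direction = direction,
                       stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("signed_gene_set", "data.frame"))
}
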