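# Plain-text on-disk formats:
#   bulk  -> counts.tsv (first column gene_id) + samples.tsv
#   sc    -> one directory per sample: matrix.mtx, features.tsv, barcodes.tsv
# (10x-style triplet, 1-based coordinate integer MTX, genes x cells).

#' Write an experiment to plain-text fixtures
#'
#' Bulk experiments become `counts.tsv` (first column `gene_id`, one column
#' per sample) plus `samples.tsv`; single-cell experiments become one
#' sub-directory per sample holding `matrix.mtx`, `features.tsv`
#' (gene_id, gene_name) and `barcodes.tsv`. Output round-trips losslessly
#' through [read_bulk_experiment()] / [read_sc_experiment()].
#'
#' @param experiment a `BulkExperiment` or `SCExperiment`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the character vector of files written.
#' @export
write_fixtures <- function(experiment, outdir) UseMethod("write_fixtures")

#' @export
write_fixtures.BulkExperiment <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) halt("cannot create directory: %s", outdir)
  cf <- file.path(outdir, "counts.tsv")
  sf <- file.path(outdir, "samples.tsv")
  df <- data.frame(gene_id = rownames(experiment$counts),
                   experiment$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$samples, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cf, sf))
}

#' @export
write_fixtures.SCExperiment <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) halt("cannot create directory: %s", outdir)
  out <- character(0)
  for (smp in unique(experiment$sample_of)) {
    d <- file.path(outdir, smp)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    cols <- experiment$sample_of == smp
    m <- experiment$counts[, cols, drop = FALSE]
    mf <- file.path(d, "matrix.mtx")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"), mf)
    ff <- file.path(d, "features.tsv")
    utils::write.table(experiment$features[, c("gene_id", "gene_name")], ff,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    bf <- file.path(d, "barcodes.tsv")
    writeLines(colnames(m), bf)
    out <- c(out, mf, ff, bf)
  }
  invisible(out)
}

#' Read a bulk experiment from TSV fixtures
#'
#' @param counts_tsv path to the counts TSV (first column `gene_id`).
#' @param samples_tsv path to the sample metadata TSV
#'   (`sample`, `condition`, `pair`, `timepoint`).
#' @return a [bulk_experiment()].
#' @export
read_bulk_experiment <- function(counts_tsv, samples_tsv) {
  for (f in c(counts_tsv, samples_tsv))
    if (!file.exists(f)) halt("file not found: %s", f)
  df <- utils::read.delim(counts_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(samples_tsv, stringsAsFactors = FALSE,
                               colClasses = "character")
  bulk_experiment(counts, samples)
}

#' Read a single-cell experiment from per-sample 10x-style triplets
#'
#' @param sample_dirs named character vector: sample label -> directory
#'   containing `matrix.mtx`, `features.tsv`, `barcodes.tsv`. All samples
#'   must share the same feature table.
#' @param mito_genes optional explicit mitochondrial gene-name list
#'   (default: `"MT-"` prefix rule).
#' @return an [sc_experiment()] with cells of all samples concatenated.
#' @export
read_sc_experiment <- function(sample_dirs, mito_genes = NULL) {
  if (is.null(names(sample_dirs)) || any(names(sample_dirs) == ""))
    halt("sample_dirs must be a named vector (sample label -> dir)")
  mats <- list(); feats <- NULL; labels <- character(0)
  for (smp in names(sample_dirs)) {
    d <- sample_dirs[[smp]]
    need <- file.path(d, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing)) halt("file not found: %s", missing[1])
    m <- methods::as(Matrix::readMM(need[1]), "CsparseMatrix")
    f <- utils::read.delim(need[2], header = FALSE, stringsAsFactors = FALSE)
    names(f)[1:2] <- c("gene_id", "gene_name")
    b <- readLines(need[3])
    if (nrow(m) != nrow(f)) halt("%s: matrix rows != features rows", d)
    if (ncol(m) != length(b)) halt("%s: matrix cols != barcodes", d)
    dimnames(m) <- list(f$gene_id, b)
    if (is.null(feats)) feats <- f
    else if (!identical(feats$gene_id, f$gene_id))
      halt("feature tables differ between samples")
    mats[[smp]] <- m
    labels <- c(labels, rep(smp, ncol(m)))
  }
  counts <- do.call(cbind, mats)
  sc_experiment(counts, feats, sample_of = labels, mito_genes = mito_genes)
}
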