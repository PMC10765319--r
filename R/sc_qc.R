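# Single-cell QC and depth normalization.

#' QC thresholds for cell filtering
#'
#' @param max_mito_fraction cells with a strictly greater mitochondrial
#'   count fraction are removed (default 0.10).
#' @param min_genes_detected cells detecting strictly fewer genes (nonzero
#'   counts) are removed (default 200; a cell with exactly 200 is kept).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.10, min_genes_detected = 200) {
  if (!is_prop(max_mito_fraction)) halt("max_mito_fraction must be in [0, 1]")
  if (!(is.numeric(min_genes_detected) && min_genes_detected >= 0))
    halt("min_genes_detected must be >= 0")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes_detected = as.integer(min_genes_detected)),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Removes cells whose mitochondrial fraction exceeds
#' `max_mito_fraction` or that detect fewer than `min_genes_detected`
#' genes. Cells with zero total counts are removed and counted separately.
#' The gene universe is unchanged; the operation is idempotent.
#'
#' @param experiment an [sc_experiment()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `experiment` (filtered) and `report` (list of
#'   per-criterion removal counts; a cell failing several criteria is
#'   counted in each).
#' @export
qc_filter <- function(experiment, thresholds = qc_thresholds()) {
  stopifnot(inherits(experiment, "SCExperiment"),
            inherits(thresholds, "qc_thresholds"))
  m <- experiment$counts
  total <- Matrix::colSums(m)
  mito <- Matrix::colSums(m[experiment$features$is_mito, , drop = FALSE])
  detected <- Matrix::colSums(m > 0)
  zero_total <- total == 0
  mito_frac <- ifelse(zero_total, 0, mito / pmax(total, 1))
  fail_mito <- !zero_total & mito_frac > thresholds$max_mito_fraction
  fail_genes <- !zero_total & detected < thresholds$min_genes_detected
  keep <- !(zero_total | fail_mito | fail_genes)
  filtered <- sc_experiment(m[, keep, drop = FALSE], experiment$features,
                            sample_of = experiment$sample_of[keep])
  filtered$features$is_mito <- experiment$features$is_mito
  report <- list(n_input = ncol(m),
                 n_removed_mito = sum(fail_mito),
                 n_removed_few_genes = sum(fail_genes),
                 n_removed_zero_total = sum(zero_total),
                 n_removed = sum(!keep),
                 n_kept = sum(keep),
                 thresholds = unclass(thresholds))
  list(experiment = filtered, report = report)
}

#' Depth log-normalization
#'
#' Per-cell normalization to a fixed scale factor followed by the natural
#' log: `x_gc = ln(1 + count_gc / total_c * scale_factor)`. Invariant to
#' scaling all of a cell's counts by a constant.
#'
#' @param experiment an [sc_experiment()] (QC-filtered; zero-total cells
#'   are an error).
#' @param scale_factor target per-cell total (default 1e4, i.e. counts per
#'   10k).
#' @return sparse gene x cell matrix of log-normalized expression.
#' @export
log_normalize <- function(experiment, scale_factor = 1e4) {
  stopifnot(inherits(experiment, "SCExperiment"))
  m <- experiment$counts
  total <- Matrix::colSums(m)
  if (any(total == 0))
    halt("cell(s) with zero total counts (run qc_filter first): %s",
         colnames(m)[which(total == 0)[1]])
  x <- m %*% Matrix::Diagonal(ncol(m), scale_factor / total)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(m)
  methods::as(x, "CsparseMatrix")
}
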