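# Trimmed mean of M-values (TMM) between-sample normalization.
#
# For sample j against reference r, over genes with positive counts in
# both:
#   M_g = log2((y_gj/N_j) / (y_gr/N_r))        (log ratio)
#   A_g = 0.5*log2((y_gj/N_j) * (y_gr/N_r))    (log abundance)
# The top/bottom trim_m of genes by M and trim_a by A are discarded and
# the factor is 2^(weighted mean of the remaining M), with weights the
# inverse of the asymptotic (delta-method) variance
#   w_g^-1 = (N_j - y_gj)/(N_j y_gj) + (N_r - y_gr)/(N_r y_gr).
# Factors are rescaled to geometric mean 1.

# one sample vs reference; obs/ref count vectors, n_obs/n_ref library sizes
.tmm_one <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR)) return(NA_real_)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(logR); rA <- rank(absE)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values:
#' precision-weighted mean of per-gene log ratios against a reference
#' sample after trimming extremes of the log-ratio (M) and log-abundance
#' (A) distributions. Factors multiply library sizes, so a sample whose
#' high-count genes are compositionally inflated gets a factor above 1.
#'
#' @param experiment a [bulk_experiment()].
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @param reference optional reference sample name; default is the sample
#'   whose 75th-percentile normalized count is closest to the mean of those
#'   percentiles.
#' @return list of class `norm_factors`: `lib_sizes`, `tmm_factors` (both
#'   named by sample, factors have geometric mean 1), `trim_m`, `trim_a`,
#'   `reference_sample`.
#' @export
compute_tmm_factors <- function(experiment, trim_m = 0.30, trim_a = 0.05,
                                reference = NULL) {
  stopifnot(inherits(experiment, "BulkExperiment"))
  y <- experiment$counts
  if (ncol(y) < 2) halt("need at least 2 samples")
  keep <- rowSums(y) > 0
  n_dropped <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  lib <- colSums(y)
  if (any(lib == 0)) halt("sample with all-zero counts: %s",
                          colnames(y)[which(lib == 0)[1]])
  if (is.null(reference)) {
    q75 <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, p = 0.75)
    reference <- colnames(y)[which.min(abs(q75 - mean(q75)))]
  }
  if (!reference %in% colnames(y)) halt("reference sample '%s' not found", reference)
  r <- y[, reference]
  f <- vapply(colnames(y), function(j) {
    if (j == reference) return(1)
    co <- y[, j] > 0 & r > 0
    if (!any(co)) halt("no co-expressed genes between sample '%s' and reference", j)
    .tmm_one(y[co, j], r[co], lib[j], lib[reference], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(lib_sizes = lib, tmm_factors = f,
                 trim_m = trim_m, trim_a = trim_a,
                 reference_sample = reference,
                 n_genes_dropped = n_dropped),
            class = "norm_factors")
}

#' Counts per million on TMM-effective library sizes
#'
#' `cpm_gj = (y_gj + pseudocount) / (N_j * f_j) * 1e6`.
#'
#' @param experiment a [bulk_experiment()].
#' @param factors a `norm_factors` from [compute_tmm_factors()].
#' @param pseudocount added to every count before scaling (default 0).
#' @return gene x sample numeric matrix.
#' @export
normalized_cpm <- function(experiment, factors, pseudocount = 0) {
  stopifnot(inherits(experiment, "BulkExperiment"),
            inherits(factors, "norm_factors"))
  y <- experiment$counts
  if (!all(colnames(y) %in% names(factors$tmm_factors)))
    halt("factors were not computed on this experiment (sample mismatch)")
  eff <- factors$lib_sizes[colnames(y)] * factors$tmm_factors[colnames(y)]
  sweep(y + pseudocount, 2, eff, "/") * 1e6
}
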