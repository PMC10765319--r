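# Downsampling-balanced Wilcoxon differential expression.
#
# The case group (e.g. PIM- cells of the TKD sample) is compared against a
# larger control group (all Scr cells). The control is downsampled without
# replacement n_subsets times to the case size; each subset is tested per
# gene with a two-sided Wilcoxon rank-sum on log-normalized expression,
# BH-corrected, and a per-subset log2FC computed on back-transformed
# means. The aggregate call is signif_prop: the proportion of subsets in
# which a gene passes FDR < 0.05 and |log2FC| > 0.24.

#' Settings for the downsampling-balanced DE
#'
#' @param n_subsets number of control downsamplings (default 100).
#' @param fdr_threshold per-subset BH FDR cutoff inside signif_prop
#'   (default 0.05).
#' @param log2fc_threshold per-subset log2FC cutoff inside signif_prop
#'   (default 0.24).
#' @param min_detection_fraction a gene is tested in a subset only if
#'   detected (nonzero) in at least this fraction of cells in either group
#'   (default 0.10; set 0 to disable).
#' @param pseudocount added to back-transformed group means before the
#'   log2 ratio (default 1).
#' @param signed if `TRUE`, signif_prop counts only subsets with
#'   `log2FC > log2fc_threshold` (signed); default `FALSE` counts
#'   `|log2FC| > log2fc_threshold`.
#' @param exact_max largest per-group size for which the exact rank-sum
#'   distribution is used when there are no ties (default 25); larger
#'   groups or ties use the normal approximation with tie and continuity
#'   correction.
#' @param keep_subsets keep the per-subset p/FDR/log2FC matrices in the
#'   result (default TRUE).
#' @param seed master seed; each subset draws from an independent derived
#'   sub-seed, so results do not depend on evaluation order.
#' @return a `downsample_de_config` list.
#' @export
downsample_de_config <- function(n_subsets = 100, fdr_threshold = 0.05,
                                 log2fc_threshold = 0.24,
                                 min_detection_fraction = 0.10,
                                 pseudocount = 1, signed = FALSE,
                                 exact_max = 25, keep_subsets = TRUE,
                                 seed = 1L) {
  if (!is_count(n_subsets)) halt("n_subsets must be a positive integer")
  if (!(fdr_threshold > 0) || !(log2fc_threshold > 0))
    halt("thresholds must be positive")
  if (!is_prop(min_detection_fraction))
    halt("min_detection_fraction must be in [0, 1]")
  structure(list(n_subsets = as.integer(n_subsets),
                 fdr_threshold = fdr_threshold,
                 log2fc_threshold = log2fc_threshold,
                 min_detection_fraction = min_detection_fraction,
                 pseudocount = pseudocount, signed = isTRUE(signed),
                 exact_max = as.integer(exact_max),
                 keep_subsets = isTRUE(keep_subsets),
                 seed = as.integer(seed)),
            class = "downsample_de_config")
}

#' Two-sided Wilcoxon rank-sum p-value for each row of a matrix
#'
#' Columns `1..n1` form group 1, the rest group 2. Uses the exact
#' rank-sum distribution when both groups have at most `exact_max`
#' observations and the row has no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param m numeric matrix (features x observations).
#' @param n1 size of the first group.
#' @param exact_max exact-mode size limit (default 25).
#' @return numeric vector of two-sided p-values, one per row.
#' @export
wilcox_rows <- function(m, n1, exact_max = 25) {
  m <- as.matrix(m)
  n <- ncol(m); n2 <- n - n1
  if (n1 < 1 || n2 < 1) halt("both groups must be non-empty")
  vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- any(duplicated(v))
    if (!ties && n1 <= exact_max && n2 <= exact_max) {
      p <- if (U > n1 * n2 / 2)
        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(U, n1, n2)
      return(min(2 * p, 1))
    }
    tl <- rle(sort.int(v))$lengths
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tl^3 - tl) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)     # all values identical
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(2 * stats::pnorm(-abs(z)), 1)
  }, numeric(1))
}

# log2 ratio of back-transformed group means with pseudocount
.log2fc_rows <- function(x_case, x_ctrl, pseudocount) {
  mc <- Matrix::rowMeans(expm1_sparse(x_case))
  mr <- Matrix::rowMeans(expm1_sparse(x_ctrl))
  log2((mc + pseudocount) / (mr + pseudocount))
}

# expm1 on a sparse matrix without densifying
expm1_sparse <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    x@x <- expm1(x@x)
    x
  } else expm1(x)
}

#' Downsampling-balanced Wilcoxon differential expression
#'
#' The larger control group is downsampled without replacement to the case
#' size `n_subsets` times; each subset is analysed independently (gene
#' detection filter, per-gene two-sided Wilcoxon rank-sum on log-normalized
#' values, BH correction across tested genes, log2FC of back-transformed
#' group means) and the results aggregated as the mean log2FC and
#' signif_prop — the proportion of subsets in which the gene passed
#' FDR < `fdr_threshold` and |log2FC| > `log2fc_threshold`. If the groups
#' are already balanced every subset is the full control set.
#'
#' @param case_cells,ctrl_cells barcodes of the two groups (case is
#'   typically the smaller; groups are swapped internally if reversed, and
#'   log2FC is always case over control).
#' @param expr log-normalized gene x cell matrix from [log_normalize()].
#' @param config a [downsample_de_config()].
#' @return data.frame of class `downsample_de_table`: `gene`,
#'   `mean_log2fc` (mean over subsets where tested), `signif_prop`,
#'   `median_fdr`, `n_subsets_qualifying`, `n_subsets_tested`,
#'   `never_tested`. If `config$keep_subsets`, matrices `p`, `fdr`,
#'   `log2fc` (gene x subset) are attached as attributes.
#' @export
downsample_balanced_de <- function(case_cells, ctrl_cells, expr,
                                   config = downsample_de_config()) {
  stopifnot(inherits(config, "downsample_de_config"))
  missing <- setdiff(c(case_cells, ctrl_cells), colnames(expr))
  if (length(missing))
    halt("cell(s) not in expression matrix: %s", paste(utils::head(missing, 3), collapse = ", "))
  if (length(intersect(case_cells, ctrl_cells)))
    halt("case and control groups overlap")
  if (length(case_cells) > length(ctrl_cells)) {
    # symmetric handling: always downsample the larger group
    tmp <- case_cells; case_cells <- ctrl_cells; ctrl_cells <- tmp
    flip <- TRUE
  } else flip <- FALSE
  n_case <- length(case_cells)
  if (n_case < 2) halt("case group must have at least 2 cells")

  genes <- rownames(expr)
  ng <- length(genes)
  x_case <- expr[, case_cells, drop = FALSE]
  x_ctrl_all <- expr[, ctrl_cells, drop = FALSE]
  det_case <- Matrix::rowMeans(x_case > 0)
  dense_case <- as.matrix(x_case)

  seeds <- derive_seeds(config$seed, config$n_subsets)
  P <- FDR <- LFC <- matrix(NA_real_, ng, config$n_subsets,
                            dimnames = list(genes, NULL))
  for (i in seq_len(config$n_subsets)) {
    set.seed(seeds[i])
    sub <- sample(seq_along(ctrl_cells), n_case, replace = FALSE)
    x_ctrl <- x_ctrl_all[, sub, drop = FALSE]
    det_ctrl <- Matrix::rowMeans(x_ctrl > 0)
    test <- det_case >= config$min_detection_fraction |
            det_ctrl >= config$min_detection_fraction
    if (!any(test)) next
    m <- cbind(dense_case[test, , drop = FALSE],
               as.matrix(x_ctrl[test, , drop = FALSE]))
    p <- wilcox_rows(m, n_case, config$exact_max)
    P[test, i] <- p
    FDR[test, i] <- bh_fdr(p)
    LFC[test, i] <- .log2fc_rows(x_case[test, , drop = FALSE],
                                 x_ctrl[test, , drop = FALSE],
                                 config$pseudocount)
  }
  if (flip) LFC <- -LFC

  lfc_pass <- if (config$signed) LFC > config$log2fc_threshold
              else abs(LFC) > config$log2fc_threshold
  qual <- (FDR < config$fdr_threshold) & lfc_pass
  n_qual <- rowSums(qual, na.rm = TRUE)
  n_tested <- rowSums(!is.na(P))
  out <- data.frame(gene = genes,
                    mean_log2fc = rowMeans(LFC, na.rm = TRUE),
                    signif_prop = n_qual / config$n_subsets,
                    median_fdr = apply(FDR, 1, stats::median, na.rm = TRUE),
                    n_subsets_qualifying = n_qual,
                    n_subsets_tested = n_tested,
                    never_tested = n_tested == 0L,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$mean_log2fc[out$never_tested] <- NA_real_
  out$signif_prop[out$never_tested] <- 0
  res <- structure(out, n_case = n_case, n_ctrl = length(ctrl_cells),
                   flipped = flip, config = config,
                   class = c("downsample_de_table", "data.frame"))
  if (config$keep_subsets) {
    attr(res, "p") <- P; attr(res, "fdr") <- FDR; attr(res, "log2fc") <- LFC
  }
  res
}

#' Call DE genes from a downsampling table
#'
#' @param table a `downsample_de_table`.
#' @param signif_prop_min minimum signif_prop for a call (e.g. 0.95);
#'   genes at or above the threshold are returned, tagged by the sign of
#'   their mean log2FC.
#' @return a [signed_gene_set()] with provenance `"sc"`.
#' @export
call_de_genes <- function(table, signif_prop_min) {
  stopifnot(inherits(table, "downsample_de_table"),
            is.numeric(signif_prop_min), length(signif_prop_min) == 1L)
  keep <- !table$never_tested & table$signif_prop >= signif_prop_min
  signed_gene_set(table$gene[keep],
                  ifelse(table$mean_log2fc[keep] >= 0, "up", "down"),
                  provenance = "sc")
}
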