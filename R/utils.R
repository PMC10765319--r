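# Internal helpers shared across modules.

#' Derive independent sub-seeds from a master seed
#'
#' All stochastic stages (bootstrap resampling, permutations, downsampling
#' subsets, per-sample simulation) draw their own seed from the master seed
#' up front, so results are independent of evaluation order and reproducible.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31-1)`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment of a p-value vector; thin wrapper over
#' [stats::p.adjust()] so every module corrects for multiple testing through
#' one audited path. `NA` p-values propagate as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (FDR), same length as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 1.0))
bh_fdr <- function(p) {
  stopifnot(is.numeric(p))
  stats::p.adjust(p, method = "BH")
}

# stop() with a consistent prefix-free message, no call in the condition
halt <- function(...) stop(sprintf(...), call. = FALSE)

is_prop <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
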