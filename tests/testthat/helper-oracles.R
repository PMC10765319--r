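# Independent reference implementations used as oracles. These are coded
# from the formulas directly, in a deliberately plain style, and stay
# separate from the package's own code paths.

# Brute-force TMM: per-sample trimmed precision-weighted mean of M values
# against the reference, then factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)
  if (is.null(reference)) {
    p75 <- sapply(seq_len(ncol(counts)),
                  function(j) quantile(counts[, j] / lib[j], 0.75))
    reference <- which.min(abs(p75 - mean(p75)))
  } else reference <- match(reference, colnames(counts))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == reference) { f[j] <- 1; next }
    y <- counts[, j]; r <- counts[, reference]
    use <- y > 0 & r > 0
    y <- y[use]; r <- r[use]
    M <- log2((y / lib[j]) / (r / lib[reference]))
    A <- 0.5 * log2((y / lib[j]) * (r / lib[reference]))
    w <- 1 / ((lib[j] - y) / (lib[j] * y) + (lib[reference] - r) / (lib[reference] * r))
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(M); ra_ <- rank(A)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    f[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed).
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Hand-coded Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small hand-built single-cell experiment. `cells` is a list of integer
# count vectors (length n_genes); the first `n_mito` genes are
# mitochondrial.
make_sc_toy <- function(cells, n_genes, n_mito = 2,
                        sample_of = rep("Scr", length(cells)),
                        gene_names = NULL) {
  if (is.null(gene_names))
    gene_names <- c(sprintf("MT-%d", seq_len(n_mito)),
                    sprintf("G%03d", seq_len(n_genes - n_mito)))
  m <- do.call(cbind, cells)
  rownames(m) <- gene_names
  colnames(m) <- sprintf("cell%02d", seq_along(cells))
  sc_experiment(m,
                data.frame(gene_id = gene_names, gene_name = gene_names),
                sample_of = sample_of)
}

# NB count matrix used for TMM oracle comparisons.
random_nb_counts <- function(n_genes = 200, n_samples = 6, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(80), 1.3)
  lib <- runif(n_samples, 0.5, 2)
  m <- sapply(seq_len(n_samples),
              function(j) rnbinom(n_genes, size = 5, mu = base * lib[j]))
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(n_samples)))
  m
}

# Wrap a raw count matrix as a minimal paired BulkExperiment (pairing
# metadata synthesized; only normalization-level tests use this).
as_bulk <- function(counts) {
  ns <- ncol(counts)
  bulk_experiment(counts, data.frame(
    sample = colnames(counts),
    condition = rep(c("Scr", "TKD"), length.out = ns),
    pair = rep(seq_len(ceiling(ns / 2)), each = 2)[seq_len(ns)],
    timepoint = "6h"))
}
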