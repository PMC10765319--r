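# Paired reproducibility-optimized testing.
#
# Statistic family over per-pair log2 cpm differences Delta_gi:
#   d_g = |mean(Delta_g.)| / (alpha1 + alpha2 * SE(Delta_g.))
# The (alpha1, alpha2) member and a top-list size k are chosen to maximize
#   Z_k = (R_k - R0_k) / sd(R_k)
# where R_k is the mean top-k overlap proportion between two bootstrap
# pair-resamplings of the data and R0_k the same computed on sign-flip
# randomized data (the paired null). FDR comes from sign-flip permutations
# of the chosen statistic.

#' Settings for the paired reproducibility-optimized test
#'
#' @param B bootstrap resampling rounds used to estimate top-list
#'   reproducibility (default 500).
#' @param alpha1_grid,alpha2_grid grids for the statistic family
#'   `d = |m| / (alpha1 + alpha2 * s)`; defaults: alpha1 from 0 to 0.5 in
#'   51 steps, alpha2 in {0, 1}. alpha2 = 0 gives a pure fold-change
#'   ranking, alpha1 = 0 with alpha2 = 1 a t-like statistic.
#' @param k_grid top-list sizes scanned; default geometric spacing from 10
#'   to half the number of genes (resolved at run time).
#' @param n_perm sign-flip permutations for FDR estimation (default 500).
#' @param pseudocount added to cpm before log2 in the paired differences
#'   (default 0.5).
#' @param seed master seed for bootstrap, null and permutation streams.
#' @return a `rots_config` list.
#' @export
rots_config <- function(B = 500, alpha1_grid = seq(0, 0.5, length.out = 51),
                        alpha2_grid = c(0, 1), k_grid = NULL,
                        n_perm = 500, pseudocount = 0.5, seed = 1L) {
  if (!is_count(B) || B < 2) halt("B must be an integer >= 2")
  if (!length(alpha1_grid) || !length(alpha2_grid)) halt("alpha grids must be non-empty")
  if (any(alpha1_grid < 0) || any(alpha2_grid < 0)) halt("alpha grids must be non-negative")
  if (!is_count(n_perm)) halt("n_perm must be a positive integer")
  structure(list(B = as.integer(B), alpha1_grid = alpha1_grid,
                 alpha2_grid = alpha2_grid, k_grid = k_grid,
                 n_perm = as.integer(n_perm), pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "rots_config")
}

# top-list position of each gene under statistic d (ties broken by stable
# gene order)
.top_pos <- function(d) {
  pos <- integer(length(d))
  pos[order(-d, seq_along(d))] <- seq_along(d)
  pos
}

# overlap proportion of top-k lists for every k in k_grid, given two
# position vectors
.topk_overlap <- function(pos1, pos2, k_grid, n) {
  worse <- pmax(pos1, pos2)
  cum <- cumsum(tabulate(worse, nbins = n))
  cum[k_grid] / k_grid
}

# random sign-flip pattern over pairs, excluding the two trivial patterns
# (identity and global flip) which reproduce the observed |statistic|
# exactly and would floor the permutation FDR at 2/2^n_pairs
.rand_flips <- function(np) {
  repeat {
    f <- sample(c(-1, 1), np, replace = TRUE)
    if (length(unique(f)) > 1L) return(f)
  }
}

# the (alpha1, alpha2) grid as a matrix, deduplicated by ranking class:
# for alpha2 = 0 the ranking is |m|/alpha1, identical for every alpha1 > 0,
# so a single representative is evaluated; (0, 0) is degenerate and dropped.
.alpha_grid <- function(a1g, a2g) {
  g <- expand.grid(alpha1 = a1g, alpha2 = a2g)
  g <- g[!(g$alpha1 == 0 & g$alpha2 == 0), , drop = FALSE]
  zero2 <- g$alpha2 == 0
  if (any(zero2)) {
    rep1 <- min(g$alpha1[zero2 & g$alpha1 > 0], 1)
    g <- rbind(g[!zero2, , drop = FALSE], data.frame(alpha1 = rep1, alpha2 = 0))
  }
  as.matrix(g)
}

#' Paired reproducibility-optimized differential expression test
#'
#' Tests TKD vs Scr within donor pairs at one timepoint. Per-gene paired
#' differences of log2 TMM-normalized cpm are summarized by the modified
#' statistic `d = |m| / (alpha1 + alpha2 * s)` whose parameters, together
#' with a top-list size, are selected to maximize the bootstrap
#' reproducibility of the top list relative to a sign-flip null. FDR is
#' estimated by sign-flip permutations of the chosen statistic and
#' monotonized to be non-increasing in `d`.
#'
#' @param experiment a [bulk_experiment()].
#' @param factors its [compute_tmm_factors()] result.
#' @param config a [rots_config()].
#' @param timepoint the timepoint label to test.
#' @return data.frame of class `bulk_de_table`: `gene`, `mean_log2fc`,
#'   `scale` (paired SE), `statistic`, `fdr`, `fc` (`2^|mean_log2fc|`),
#'   `direction`. Attributes `alpha1`, `alpha2`, `k_opt`, `z_opt`,
#'   `timepoint`, `n_pairs`.
#' @export
paired_rots_test <- function(experiment, factors, config = rots_config(),
                             timepoint) {
  stopifnot(inherits(experiment, "BulkExperiment"),
            inherits(config, "rots_config"))
  meta <- experiment$samples
  sel <- meta$timepoint == timepoint
  if (!any(sel)) halt("timepoint '%s' not present", timepoint)
  meta <- meta[sel, , drop = FALSE]
  pairs <- sort(unique(meta$pair))
  if (length(pairs) < 2) halt("paired SE undefined with fewer than 2 pairs")
  tkd <- meta$sample[meta$condition == "TKD"][match(pairs, meta$pair[meta$condition == "TKD"])]
  scr <- meta$sample[meta$condition == "Scr"][match(pairs, meta$pair[meta$condition == "Scr"])]
  if (anyNA(tkd) || anyNA(scr))
    halt("every pair needs both TKD and Scr samples at timepoint '%s'", timepoint)

  cpm <- normalized_cpm(experiment, factors, pseudocount = config$pseudocount)
  cpm <- cpm[rowSums(experiment$counts) > 0, , drop = FALSE]
  D <- log2(cpm[, tkd, drop = FALSE]) - log2(cpm[, scr, drop = FALSE])
  genes <- rownames(D)
  ng <- nrow(D); np <- ncol(D)

  k_grid <- config$k_grid
  if (is.null(k_grid))
    k_grid <- unique(pmin(round(exp(seq(log(10), log(max(ng / 2, 10)),
                                        length.out = 10))), ng))
  if (any(k_grid > ng)) halt("k_grid entries exceed the number of genes")
  k_grid <- sort(unique(as.integer(k_grid)))

  agrid <- .alpha_grid(config$alpha1_grid, config$alpha2_grid)
  n_a <- nrow(agrid)

  seeds <- derive_seeds(config$seed, 3L)
  d_of <- function(m, s, a1, a2) {
    den <- a1 + a2 * s
    d <- abs(m) / den
    d[m == 0] <- 0                 # no shift, no evidence (covers 0/0)
    d[den == 0 & m != 0] <- Inf
    d
  }
  ms <- function(Di) {
    n <- ncol(Di)
    m <- rowMeans(Di)
    v <- (rowSums(Di * Di) - n * m * m) / (n - 1)
    list(m = m, s = sqrt(pmax(v, 0) / n))   # paired standard error
  }

  overlap_pass <- function(D, seed, flip_first) {
    set.seed(seed)
    ov <- array(NA_real_, c(n_a, length(k_grid), config$B))
    for (b in seq_len(config$B)) {
      Db <- if (flip_first) sweep(D, 2, .rand_flips(np), "*") else D
      x1 <- ms(Db[, sample.int(np, np, replace = TRUE), drop = FALSE])
      x2 <- ms(Db[, sample.int(np, np, replace = TRUE), drop = FALSE])
      for (a in seq_len(n_a)) {
        p1 <- .top_pos(d_of(x1$m, x1$s, agrid[a, 1], agrid[a, 2]))
        p2 <- .top_pos(d_of(x2$m, x2$s, agrid[a, 1], agrid[a, 2]))
        ov[a, , b] <- .topk_overlap(p1, p2, k_grid, ng)
      }
    }
    ov
  }

  ov_obs <- overlap_pass(D, seeds[1], flip_first = FALSE)
  ov_null <- overlap_pass(D, seeds[2], flip_first = TRUE)

  R <- apply(ov_obs, c(1, 2), mean)
  R0 <- apply(ov_null, c(1, 2), mean)
  S <- apply(ov_obs, c(1, 2), stats::sd)
  Z <- (R - R0) / pmax(S, 1e-8)
  best <- which(Z == max(Z), arr.ind = TRUE)[1, ]
  a_opt <- agrid[best[1], ]
  k_opt <- k_grid[best[2]]

  obs <- ms(D)
  d <- d_of(obs$m, obs$s, a_opt[1], a_opt[2])

  # permutation FDR: q_g = E_perm[#{d_perm >= d_g}] / #{d_obs >= d_g}
  set.seed(seeds[3])
  d_sorted <- sort(d)
  n_ge <- function(vals_sorted, t) length(vals_sorted) -
    findInterval(t, vals_sorted, left.open = TRUE)
  fp <- numeric(ng)
  for (p in seq_len(config$n_perm)) {
    Dp <- sweep(D, 2, .rand_flips(np), "*")
    xp <- ms(Dp)
    dp_sorted <- sort(d_of(xp$m, xp$s, a_opt[1], a_opt[2]))
    fp <- fp + n_ge(dp_sorted, d)
  }
  fp <- fp / config$n_perm
  rg <- n_ge(d_sorted, d)
  q <- pmin(fp / rg, 1)
  ord <- order(-d, seq_along(d))
  q[ord] <- cummax(q[ord])

  out <- data.frame(gene = genes, mean_log2fc = obs$m, scale = obs$s,
                    statistic = d, fdr = q, fc = 2^abs(obs$m),
                    direction = ifelse(obs$m >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, alpha1 = unname(a_opt[1]), alpha2 = unname(a_opt[2]),
            k_opt = k_opt, z_opt = max(Z), timepoint = timepoint,
            n_pairs = np, class = c("bulk_de_table", "data.frame"))
}
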