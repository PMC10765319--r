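# Bulk arm: TMM normalization against a brute-force oracle, cpm scaling,
# the paired reproducibility-optimized test, threshold selection,
# z-scores and timepoint concordance.

test_that("TMM factors are 1 under symmetry and pure depth scaling", {
  m <- matrix(rep(c(5L, 20L, 100L, 7L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  f <- compute_tmm_factors(as_bulk(m))
  expect_equal(unname(f$tmm_factors), rep(1, 4))

  set.seed(1)
  base <- rnbinom(300, size = 5, mu = 60) + 1L
  m2 <- cbind(s1 = base, s2 = 2L * base)
  rownames(m2) <- paste0("g", seq_along(base))
  f2 <- compute_tmm_factors(as_bulk(m2))
  expect_equal(unname(f2$tmm_factors), c(1, 1))
})

test_that("TMM matches the brute-force trimmed weighted-mean oracle", {
  for (s in 1:5) {
    m <- random_nb_counts(150, 6, seed = s)
    got <- compute_tmm_factors(as_bulk(m))
    expect_equal(unname(got$tmm_factors), oracle_tmm(m), tolerance = 1e-10)
  }
  # planted composition bias: 5% of genes x8 in one sample
  m <- random_nb_counts(200, 6, seed = 99)
  idx <- sample(200, 10)
  m[idx, 1] <- m[idx, 1] * 8L
  got <- compute_tmm_factors(as_bulk(m))
  expect_equal(unname(got$tmm_factors), oracle_tmm(m), tolerance = 1e-10)
  # the biased sample is scaled down relative to the rest
  expect_lt(got$tmm_factors[1] / exp(mean(log(got$tmm_factors[-1]))), 1)
})

test_that("TMM cross-checks against edgeR's implementation", {
  library(edgeR)
  for (s in c(3, 17)) {
    m <- random_nb_counts(200, 6, seed = s)
    ours <- compute_tmm_factors(as_bulk(m))
    theirs <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(ours$tmm_factors), unname(theirs), tolerance = 1e-10)
  }
})

test_that("TMM errors are informative", {
  m <- matrix(c(0L, 5L, 9L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(compute_tmm_factors(as_bulk(m)), "co-expressed")
  expect_error(compute_tmm_factors(as_bulk(random_nb_counts(50, 4)),
                                   reference = "nope"), "reference")
})

test_that("normalized cpm has the documented scale and invariances", {
  m <- matrix(c(0L, 5L, 10L, 5L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ex <- as_bulk(m)
  f <- compute_tmm_factors(ex)
  cpm <- normalized_cpm(ex, f, pseudocount = 0)
  expect_equal(cpm["g1", "s1"], 0)
  # forced unit scaling: y / (N f) * 1e6
  eff <- f$lib_sizes * f$tmm_factors
  expect_equal(cpm["g2", "s1"], 5 / eff[["s1"]] * 1e6)
  # doubling counts and library sizes leaves cpm unchanged
  ex2 <- as_bulk(2L * m)
  f2 <- compute_tmm_factors(ex2)
  expect_equal(normalized_cpm(ex2, f2, 0), cpm, tolerance = 1e-12)
})

make_paired_counts <- function(delta_gene = NULL, n_genes = 60, n_pairs = 4,
                               seed = 1) {
  # equal-composition base counts with optional planted multiplicative
  # shift of one gene in all TKD samples
  set.seed(seed)
  base <- rnbinom(n_genes, size = 20, mu = 200) + 50L
  samples <- expand.grid(pair = seq_len(n_pairs), condition = c("Scr", "TKD"),
                         stringsAsFactors = FALSE)
  samples$timepoint <- "6h"
  samples$sample <- sprintf("%s_p%d", samples$condition, samples$pair)
  counts <- sapply(seq_len(nrow(samples)), function(j) {
    y <- base + sample(-3:3, n_genes, replace = TRUE)
    if (!is.null(delta_gene) && samples$condition[j] == "TKD")
      y[delta_gene] <- y[delta_gene] * 8L
    y
  })
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)), samples$sample)
  bulk_experiment(counts, samples)
}

test_that("zero-difference genes get statistic 0 and FDR 1", {
  ex <- make_paired_counts(seed = 5)
  # make all samples byte-identical: every gene has zero paired difference
  ex$counts[] <- ex$counts[, 1]
  f <- compute_tmm_factors(ex)
  tab <- paired_rots_test(ex, f, rots_config(B = 50, n_perm = 50, seed = 1), "6h")
  expect_true(all(tab$statistic == 0))
  expect_true(all(tab$fdr == 1))
})

test_that("a dominant constant-shift gene ranks first for every family member", {
  ex <- make_paired_counts(delta_gene = 7, seed = 6)
  f <- compute_tmm_factors(ex)
  tab <- paired_rots_test(ex, f, rots_config(B = 50, n_perm = 100, seed = 2), "6h")
  i <- which(tab$gene == "g007")
  # dominance holds across the whole (alpha1, alpha2) family, not just the
  # selected member: check d on a grid from the table's m and s
  for (a1 in c(0.01, 0.1, 0.5)) for (a2 in c(0, 1)) {
    d <- abs(tab$mean_log2fc) / (a1 + a2 * tab$scale)
    expect_equal(which.max(d), i)
  }
  expect_equal(which.min(tab$fdr), i)
  expect_lt(tab$fdr[i], 0.1)
  expect_equal(tab$direction[i], "up")
  expect_gt(tab$fc[i], 4)
})

test_that("the paired test does not inflate calls under a global null", {
  frac <- vapply(1:10, function(s) {
    g <- generate_bulk(bulk_sim_config(n_genes = 300, de_fraction = 0,
                                       timepoints = "6h", seed = 600 + s))
    f <- compute_tmm_factors(g$experiment)
    tab <- paired_rots_test(g$experiment, f,
                            rots_config(B = 100, n_perm = 100, seed = s), "6h")
    mean(tab$fdr < 0.1)
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})

test_that("the paired test is deterministic given its seed", {
  ex <- make_paired_counts(delta_gene = 3, seed = 9)
  f <- compute_tmm_factors(ex)
  cfg <- rots_config(B = 40, n_perm = 40, seed = 123)
  t1 <- paired_rots_test(ex, f, cfg, "6h")
  t2 <- paired_rots_test(ex, f, cfg, "6h")
  expect_identical(t1, t2)
})

test_that("the paired test demands a complete paired design", {
  ex <- make_paired_counts(seed = 2)
  f <- compute_tmm_factors(ex)
  expect_error(paired_rots_test(ex, f, rots_config(), "24h"), "not present")
  drop <- ex$samples$sample != "TKD_p2"
  ex2 <- bulk_experiment(ex$counts[, drop], ex$samples[drop, ])
  f2 <- compute_tmm_factors(ex2)
  expect_error(paired_rots_test(ex2, f2, rots_config(), "6h"), "both TKD and Scr")
})

test_that("selection applies strict FDR and fold-change thresholds", {
  tab <- structure(data.frame(
    gene = c("a", "b", "c", "d", "e"),
    mean_log2fc = c(0.6, -0.6, 0.6, 0.2, 1.0),
    scale = 0.1, statistic = 1,
    fdr = c(0.05, 0.05, 0.10, 0.05, 0.20),
    fc = 2^abs(c(0.6, -0.6, 0.6, 0.2, 1.0)),
    direction = c("up", "down", "up", "up", "up"),
    stringsAsFactors = FALSE), timepoint = "6h",
    class = c("bulk_de_table", "data.frame"))
  sel <- select_de(tab)                       # fdr < 0.1, fc > 1.4
  expect_setequal(sel$gene, c("a", "b"))      # c: fdr == 0.1 excluded; d: fc
  expect_equal(sel$direction[sel$gene == "b"], "down")
  relaxed <- select_de(tab, fdr_max = 0.25)
  expect_setequal(relaxed$gene, c("a", "b", "c", "e"))
  # exact boundary: fc == 1.4 is excluded ("above 1.4" is strict)
  tab$fc[1] <- 1.4
  expect_false("a" %in% select_de(tab)$gene)
})

test_that("selection is monotone in both thresholds", {
  set.seed(31)
  tab <- structure(data.frame(
    gene = sprintf("g%02d", 1:50),
    mean_log2fc = rnorm(50), scale = 0.1, statistic = 1,
    fdr = runif(50), fc = 2^abs(rnorm(50)),
    direction = sample(c("up", "down"), 50, TRUE),
    stringsAsFactors = FALSE), timepoint = "6h",
    class = c("bulk_de_table", "data.frame"))
  for (i in 1:20) {
    f1 <- runif(1); f2 <- runif(1)
    c1 <- runif(1, 1, 3); c2 <- runif(1, 1, 3)
    a <- select_de(tab, min(f1, f2), max(c1, c2))
    b <- select_de(tab, max(f1, f2), min(c1, c2))
    expect_true(all(a$gene %in% b$gene))
  }
})

test_that("z-scoring standardizes rows and rejects constant genes", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 6))
  z <- zscore_matrix(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  expect_error(zscore_matrix(rbind(a = c(1, 1, 1))), "zero-variance.*a")
  expect_error(zscore_matrix(m, "zz"), "not in matrix")
})

test_that("timepoint concordance keeps matching directions only", {
  s6 <- signed_gene_set(c("A", "B"), c("up", "down"), "bulk_6h")
  s24 <- signed_gene_set(c("A", "B"), c("up", "up"), "bulk_24h")
  expect_equal(common_direction_genes(s6, s24)$gene, "A")
  expect_equal(nrow(common_direction_genes(
    s6, signed_gene_set(c("X", "Y"), "up"))), 0)
  expect_equal(common_direction_genes(s6, s6)$gene, s6$gene)  # idempotent
})
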