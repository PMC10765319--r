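# Single-cell arm: QC boundaries and idempotence, log-normalization,
# marker classification, the rank-sum machinery against exact
# enumeration, and the downsampling-balanced DE.

test_that("QC removes exactly the failing cells at the stated boundaries", {
  n_genes <- 250
  mk_cell <- function(n_detected, mito_counts = c(0L, 0L)) {
    v <- integer(n_genes)
    v[1:2] <- mito_counts
    extra <- n_detected - sum(mito_counts > 0)
    if (extra > 0) v[2 + seq_len(extra)] <- 1L
    v
  }
  cells <- list(
    ok        = mk_cell(210),
    mito_high = c(30L, 0L, rep(1L, 220), integer(n_genes - 222)),  # 30/250 = 0.12
    mito_edge = c(25L, 0L, rep(1L, 225), integer(n_genes - 227)),  # 25/250 = 0.10
    few       = mk_cell(199),
    edge      = mk_cell(200),
    empty     = integer(n_genes))
  toy <- make_sc_toy(cells, n_genes)
  res <- qc_filter(toy, qc_thresholds())
  kept <- colnames(res$experiment$counts)
  expect_setequal(kept, c("cell01", "cell03", "cell05"))  # ok, mito_edge, edge
  expect_equal(res$report$n_removed_mito, 1)
  expect_equal(res$report$n_removed_few_genes, 1)
  expect_equal(res$report$n_removed_zero_total, 1)
  expect_equal(res$report$n_removed, 3)

  # idempotence and identity on clean data
  res2 <- qc_filter(res$experiment, qc_thresholds())
  expect_identical(as.matrix(res2$experiment$counts),
                   as.matrix(res$experiment$counts))
  expect_equal(res2$report$n_removed, 0)
})

test_that("log-normalization follows ln(1 + count/total * 1e4)", {
  m <- matrix(c(10L, 9990L, 0L,
                20L, 19980L, 0L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  toy <- sc_experiment(m, data.frame(gene_id = rownames(m),
                                     gene_name = rownames(m)),
                       sample_of = c("Scr", "Scr"))
  x <- log_normalize(toy)
  expect_equal(x["g1", "c1"], log(1 + 10))       # 10 of 10000
  expect_equal(x["g3", "c1"], 0)
  # c2 is c1 scaled by 2: identical normalized values
  expect_equal(as.numeric(x[, "c2"]), as.numeric(x[, "c1"]))

  m0 <- m; m0[, 2] <- 0L
  toy0 <- sc_experiment(m0, data.frame(gene_id = rownames(m), gene_name = rownames(m)),
                        sample_of = c("Scr", "Scr"))
  expect_error(log_normalize(toy0), "zero total")
})

test_that("PIM-negative means exactly zero across all three targets", {
  genes <- c("PIM1", "PIM2", "PIM3", "TBX21", "RORA", "OTHER")
  m <- cbind(c1 = c(0L, 0L, 0L, 0L, 3L, 5L),
             c2 = c(1L, 0L, 0L, 1L, 0L, 5L),
             c3 = c(0L, 0L, 0L, 2L, 0L, 1L))
  rownames(m) <- genes
  toy <- sc_experiment(m, data.frame(gene_id = genes, gene_name = genes),
                       sample_of = c("Scr", "TKD", "TKD"))
  cls <- classify_pim_negative(toy)
  expect_equal(unname(cls$is_negative), c(TRUE, FALSE, TRUE))
  expect_equal(cls$fractions$fraction[cls$fractions$sample == "TKD"], 0.5)
  states <- joint_marker_state(toy)
  expect_equal(unname(states),
               c("PIM-/TBX21-/RORA+", "PIM+/TBX21+/RORA-", "PIM-/TBX21+/RORA-"))
  # all-zero cell is all-negative
  m2 <- cbind(m, c4 = integer(6))
  toy2 <- sc_experiment(m2, data.frame(gene_id = genes, gene_name = genes),
                        sample_of = c("Scr", "TKD", "TKD", "Scr"))
  expect_equal(unname(joint_marker_state(toy2)[4]), "PIM-/TBX21-/RORA-")
  # missing marker is named in the error
  expect_error(classify_pim_negative(toy, marker_panel(c("PIM1", "PIM2", "PIMX"))),
               "PIMX")
})

test_that("classifier recovers the planted silenced fraction", {
  g <- generate_sc(sc_sim_config(n_genes = 150, n_cells_scr = 1500,
                                 n_cells_tkd = 3000, seed = 33))
  cls <- classify_pim_negative(g$experiment)
  est <- setNames(cls$fractions$fraction, cls$fractions$sample)
  expect_lt(abs(est[["TKD"]] - 0.53), 0.03)
  expect_lt(abs(est[["Scr"]] - 0.26), 0.03)
  # classifier output matches the generator's truth labels almost exactly
  truth_neg <- g$experiment$barcodes %in% g$truth$silenced_cells
  expect_gt(mean(cls$is_negative == truth_neg), 0.99)
})

test_that("rank-sum p-values agree with exact enumeration for small groups", {
  set.seed(12)
  for (rep in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- rnorm(n1 + n2)                 # continuous, no ties
    p_pkg <- wilcox_rows(matrix(v, 1), n1)
    p_oracle <- oracle_wilcox_exact(v[seq_len(n1)], v[-seq_len(n1)])
    expect_lt(abs(p_pkg - p_oracle), 1e-9)
  }
  # normal approximation is close to exact by n = 8 per group (the
  # worst case of the continuity-corrected approximation is 0.0109,
  # attained mid-distribution)
  for (rep in 1:8) {
    v <- rnorm(16)
    p_exact <- wilcox_rows(matrix(v, 1), 8)
    p_approx <- wilcox_rows(matrix(v, 1), 8, exact_max = 0)
    expect_lt(abs(p_exact - p_approx), 0.011)
  }
})

test_that("tie-corrected approximation matches the reference test with ties", {
  set.seed(99)
  for (rep in 1:10) {
    v <- sample(0:3, 40, replace = TRUE)    # heavy ties
    p_pkg <- wilcox_rows(matrix(v, 1), 20)
    p_ref <- suppressWarnings(
      wilcox.test(v[1:20], v[21:40], exact = FALSE, correct = TRUE)$p.value)
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
  # constant row: no evidence either way
  expect_equal(wilcox_rows(matrix(rep(1, 10), 1), 5), 1)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04, 1.0)
  expect_equal(bh_fdr(p), c(0.05, 0.05, 0.05, 0.05, 1.0))
  set.seed(4)
  pr <- runif(50)
  expect_equal(bh_fdr(pr), oracle_bh(pr))
})

sim_expr <- function(n_genes, n_scr, n_tkd, effect_genes = NULL, seed = 1) {
  g <- generate_sc(sc_sim_config(n_genes = n_genes, n_cells_scr = n_scr,
                                 n_cells_tkd = n_tkd,
                                 effect_genes = effect_genes, seed = seed))
  # small gene universes: scale the detected-genes rule down accordingly
  qc <- qc_filter(g$experiment, qc_thresholds(min_genes_detected = 50))
  list(expr = log_normalize(qc$experiment), ex = qc$experiment, truth = g$truth)
}

test_that("balanced groups collapse the downsampling to identical subsets", {
  s <- sim_expr(120, 60, 60, seed = 2)
  case <- s$ex$barcodes[s$ex$sample_of == "TKD"]
  ctrl <- s$ex$barcodes[s$ex$sample_of == "Scr"]
  n <- min(length(case), length(ctrl))
  de <- downsample_balanced_de(case[1:n], ctrl[1:n], s$expr,
                               downsample_de_config(n_subsets = 5, seed = 3))
  expect_true(all(de$signif_prop %in% c(0, 1)))
  P <- attr(de, "p")
  expect_true(all(apply(P, 1, function(r) length(unique(r)) == 1L)))
})

test_that("downsampling DE is deterministic and rejects bad groups", {
  s <- sim_expr(100, 80, 30, seed = 6)
  case <- s$ex$barcodes[s$ex$sample_of == "TKD"]
  ctrl <- s$ex$barcodes[s$ex$sample_of == "Scr"]
  cfg <- downsample_de_config(n_subsets = 8, seed = 11)
  d1 <- downsample_balanced_de(case, ctrl, s$expr, cfg)
  d2 <- downsample_balanced_de(case, ctrl, s$expr, cfg)
  expect_identical(d1, d2)
  expect_error(downsample_balanced_de(case[1], ctrl, s$expr, cfg), "at least 2")
  expect_error(downsample_balanced_de(case, c(ctrl, case[1]), s$expr, cfg),
               "overlap")
  expect_error(downsample_balanced_de(c("nope", case), ctrl, s$expr, cfg),
               "not in expression")
})

test_that("case/control orientation is preserved when groups are swapped", {
  eff <- c(GENE00001 = 1.5)
  s <- sim_expr(150, 400, 150, effect_genes = eff, seed = 7)
  case <- s$ex$barcodes[s$ex$sample_of == "TKD" &
                        s$ex$barcodes %in% s$truth$silenced_cells]
  ctrl <- s$ex$barcodes[s$ex$sample_of == "Scr" &
                        !s$ex$barcodes %in% s$truth$silenced_cells]
  cfg <- downsample_de_config(n_subsets = 10, seed = 5)
  fwd <- downsample_balanced_de(case, ctrl, s$expr, cfg)
  # passing the big group as "case" must still report case-over-control
  rev <- downsample_balanced_de(ctrl, case, s$expr, cfg)
  i <- which(fwd$gene == "GENE00001")
  expect_gt(fwd$mean_log2fc[i], 0.5)
  expect_lt(rev$mean_log2fc[i], -0.5)
})

test_that("signif_prop calls respond monotonically to the threshold", {
  eff <- setNames(c(1.5, -1.5), c("GENE00001", "GENE00002"))
  s <- sim_expr(150, 400, 300, effect_genes = eff, seed = 8)
  case <- s$ex$barcodes[s$ex$sample_of == "TKD" &
                        s$ex$barcodes %in% s$truth$silenced_cells]
  ctrl <- s$ex$barcodes[s$ex$sample_of == "Scr" &
                        !s$ex$barcodes %in% s$truth$silenced_cells]
  de <- downsample_balanced_de(case, ctrl, s$expr,
                               downsample_de_config(n_subsets = 20, seed = 9))
  all_called <- call_de_genes(de, 0)
  expect_setequal(all_called$gene, de$gene[!de$never_tested])
  strict <- call_de_genes(de, 1)
  expect_true(all(de$signif_prop[match(strict$gene, de$gene)] == 1))
  sizes <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(t) nrow(call_de_genes(de, t)))
  expect_true(all(diff(sizes) <= 0))
  # planted genes are recovered with the right sign
  called <- call_de_genes(de, 0.9)
  expect_true(all(names(eff) %in% called$gene))
  expect_equal(called$direction[match(names(eff), called$gene)],
               c("up", "down"))
})
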