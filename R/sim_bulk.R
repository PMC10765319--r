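# Negative-binomial simulator for the paired bulk design:
# n_pairs donor pairs x {Scr, TKD} x timepoints, with planted log2
# fold-changes in the TKD condition and multiplicative log-normal
# pair (donor) effects shared by the two conditions of a pair.

#' Configuration for the paired bulk count simulator
#'
#' Defaults emulate the study design: four donor pairs, two conditions
#' (Scr control vs PIM triple knockdown), sampled at 6 h and 24 h, with
#' 10% of genes differentially expressed at |log2FC| = 1.5 and a
#' negative-binomial dispersion of 0.1 — typical of bulk RNA-seq on
#' sorted primary T cells.
#'
#' @param n_genes number of genes.
#' @param n_pairs number of donor pairs (biological replicates).
#' @param timepoints character vector of timepoint labels.
#' @param de_fraction fraction of genes given a planted effect.
#' @param lfc_magnitude absolute planted log2 fold-change (TKD vs Scr);
#'   signs are drawn at random per gene.
#' @param dispersion negative-binomial dispersion phi (variance
#'   mu + phi*mu^2); `0` gives Poisson counts.
#' @param lib_size_range range (min, max) of per-sample library sizes,
#'   drawn uniformly.
#' @param pair_sd standard deviation (natural-log scale) of the
#'   multiplicative per-gene, per-pair donor effect shared by the two
#'   conditions of a pair.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline expression.
#' @param composition_bias optional list `list(sample =, factors =)` where
#'   `factors` is a named numeric vector of multipliers applied to the named
#'   genes in one sample only (for exercising composition-robust
#'   normalization); `sample` defaults to the first sample.
#' @param seed master seed.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_genes = 1000, n_pairs = 4,
                            timepoints = c("6h", "24h"),
                            de_fraction = 0.1, lfc_magnitude = 1.5,
                            dispersion = 0.1,
                            lib_size_range = c(8e5, 1.2e6),
                            pair_sd = 0.25,
                            baseline_meanlog = log(50), baseline_sdlog = 1.2,
                            composition_bias = NULL,
                            seed = 1L) {
  if (!is_count(n_genes)) halt("n_genes must be a positive integer")
  if (!is_count(n_pairs)) halt("n_pairs must be a positive integer")
  if (!is_prop(de_fraction)) halt("de_fraction must be in [0, 1]")
  if (de_fraction > 0 && de_fraction * n_genes < 1)
    halt("de_fraction * n_genes must be >= 1 when de_fraction > 0")
  if (!(is.numeric(lfc_magnitude) && lfc_magnitude > 0))
    halt("lfc_magnitude must be positive")
  if (!(is.numeric(dispersion) && length(dispersion) == 1L && dispersion >= 0))
    halt("dispersion must be a non-negative number")
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    halt("lib_size_range must be an increasing pair of positive sizes")
  if (!length(timepoints)) halt("at least one timepoint required")
  structure(list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
                 timepoints = as.character(timepoints),
                 de_fraction = de_fraction, lfc_magnitude = lfc_magnitude,
                 dispersion = dispersion, lib_size_range = lib_size_range,
                 pair_sd = pair_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 composition_bias = composition_bias,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a paired bulk knockdown experiment
#'
#' Counts are negative binomial with mean
#' `baseline_g * pair_effect_gi * condition_effect_g * depth_j`, where the
#' pair effect is log-normal and shared between the Scr and TKD samples of
#' a pair (this is the correlation the paired test exploits), and the
#' condition effect is `2^lfc` in TKD samples for planted genes, 1
#' otherwise. Deterministic given `config$seed`.
#'
#' @param config a [bulk_sim_config()].
#' @return list with `experiment` (a [bulk_experiment()]) and `truth`
#'   (class `synthetic_truth`: `de_genes` named vector of signed log2FC,
#'   `silenced_cells` empty for bulk, `sim_config`).
#' @export
generate_bulk <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  cf <- config
  set.seed(cf$seed)
  genes <- sprintf("GENE%05d", seq_len(cf$n_genes))
  baseline <- stats::rlnorm(cf$n_genes, cf$baseline_meanlog, cf$baseline_sdlog)
  rel <- baseline / sum(baseline)

  n_de <- floor(cf$de_fraction * cf$n_genes)
  de_genes <- numeric(0)
  if (n_de > 0) {
    idx <- sample.int(cf$n_genes, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    de_genes <- stats::setNames(sgn * cf$lfc_magnitude, genes[idx])
  }
  cond_mult <- rep(1, cf$n_genes)
  if (n_de > 0) cond_mult[match(names(de_genes), genes)] <- 2^de_genes

  grid <- expand.grid(pair = seq_len(cf$n_pairs),
                      condition = c("Scr", "TKD"),
                      timepoint = cf$timepoints,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_p%d", grid$condition, grid$timepoint, grid$pair)
  n_samp <- nrow(grid)
  lib <- round(stats::runif(n_samp, cf$lib_size_range[1], cf$lib_size_range[2]))

  # donor effect: per gene x pair x timepoint, identical for Scr and TKD
  counts <- matrix(0L, cf$n_genes, n_samp, dimnames = list(genes, grid$sample))
  for (tp in cf$timepoints) {
    pair_eff <- matrix(stats::rlnorm(cf$n_genes * cf$n_pairs, 0, cf$pair_sd),
                       cf$n_genes, cf$n_pairs)
    for (j in which(grid$timepoint == tp)) {
      mu <- rel * pair_eff[, grid$pair[j]] * lib[j]
      if (grid$condition[j] == "TKD") mu <- mu * cond_mult
      counts[, j] <- if (cf$dispersion > 0)
        stats::rnbinom(cf$n_genes, size = 1 / cf$dispersion, mu = mu)
      else stats::rpois(cf$n_genes, mu)
    }
  }

  if (!is.null(cf$composition_bias)) {
    cb <- cf$composition_bias
    smp <- if (!is.null(cb$sample)) cb$sample else grid$sample[1]
    if (!smp %in% grid$sample) halt("composition_bias sample '%s' not simulated", smp)
    tgt <- names(cb$factors)
    bad <- setdiff(tgt, genes)
    if (length(bad)) halt("composition_bias gene(s) not in universe: %s",
                          paste(bad, collapse = ", "))
    counts[tgt, smp] <- as.integer(round(counts[tgt, smp] * cb$factors))
  }

  exper <- bulk_experiment(counts, grid[, c("sample", "condition", "pair", "timepoint")])
  truth <- structure(list(de_genes = de_genes,
                          silenced_cells = character(0),
                          sim_config = cf),
                     class = "synthetic_truth")
  list(experiment = exper, truth = truth)
}
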