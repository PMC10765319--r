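# Single-cell simulator: two samples (Scr control, PIM TKD) in which a
# configured fraction of cells per sample is "silenced" — zero counts for
# all three PIM target genes — and planted effects apply only in silenced
# cells. Counts are negative binomial with per-cell depth and an optional
# logistic dropout on top.

#' Configuration for the two-sample single-cell simulator
#'
#' Defaults mirror the observed knockdown pattern: 53% of TKD cells and
#' 26% of Scr control cells have no detected transcripts of any of PIM1,
#' PIM2 and PIM3. The knockdown targets receive an elevated baseline
#' (around 10 counts per 10k) so that a non-silenced cell essentially never
#' shows an all-zero PIM triplet by chance — in real data the PIMs are
#' well-detected genes, which is what makes the zero-count classifier
#' meaningful.
#'
#' @param n_genes number of genes (including the 3 targets and the
#'   mitochondrial block).
#' @param n_cells_scr,n_cells_tkd cells per sample.
#' @param silenced_fraction_scr,silenced_fraction_tkd per-sample probability
#'   that a cell is knockdown-silenced.
#' @param kd_target_genes exactly 3 gene names jointly silenced.
#' @param effect_genes named numeric vector gene -> log2FC applied only in
#'   silenced cells.
#' @param mito_gene_fraction fraction of genes named with the `"MT-"`
#'   prefix.
#' @param mean_depth expected UMI total per cell.
#' @param depth_sdlog log-normal sd of per-cell depth.
#' @param dispersion negative-binomial dispersion phi.
#' @param dropout_shape `list(intercept =, slope =)` of a logistic
#'   detection model in log mean expression, or `NULL` to disable dropout.
#' @param kd_mode `"zero"` forces target counts to exactly 0 in silenced
#'   cells (the operational PIM- definition); `"reduced"` instead divides
#'   the target mean by `2^kd_log2fc`.
#' @param kd_log2fc reduction (log2) used when `kd_mode = "reduced"`.
#' @param target_cp10k baseline expression of the kd targets, counts per
#'   10k.
#' @param effect_cp10k baseline expression (counts per 10k) pinned for the
#'   genes named in `effect_genes`, so planted effects live on a defined,
#'   well-detected scale; `NULL` leaves their drawn baselines untouched.
#' @param seed master seed.
#' @return an `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_genes = 1500,
                          n_cells_scr = 3000, n_cells_tkd = 3000,
                          silenced_fraction_scr = 0.26,
                          silenced_fraction_tkd = 0.53,
                          kd_target_genes = c("PIM1", "PIM2", "PIM3"),
                          effect_genes = NULL,
                          mito_gene_fraction = 0.05,
                          mean_depth = 5000,
                          depth_sdlog = 0.3,
                          dispersion = 0.4,
                          dropout_shape = list(intercept = 1.5, slope = 1.5),
                          kd_mode = c("zero", "reduced"),
                          kd_log2fc = 4,
                          target_cp10k = 10,
                          effect_cp10k = 5,
                          seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_cells_scr) || !is_count(n_cells_tkd))
    halt("n_genes and cell numbers must be positive integers")
  if (!is_prop(silenced_fraction_scr) || !is_prop(silenced_fraction_tkd) ||
      !is_prop(mito_gene_fraction))
    halt("all fractions must be proportions in [0, 1]")
  if (length(kd_target_genes) != 3L)
    halt("kd_target_genes must have exactly 3 entries")
  if (!is.null(effect_genes) &&
      (is.null(names(effect_genes)) || !is.numeric(effect_genes)))
    halt("effect_genes must be a named numeric vector (gene -> log2FC)")
  if (!(is.numeric(mean_depth) && mean_depth > 0)) halt("mean_depth must be positive")
  if (!(is.numeric(dispersion) && dispersion > 0)) halt("dispersion must be positive")
  kd_mode <- match.arg(kd_mode)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_scr = as.integer(n_cells_scr),
                 n_cells_tkd = as.integer(n_cells_tkd),
                 silenced_fraction_scr = silenced_fraction_scr,
                 silenced_fraction_tkd = silenced_fraction_tkd,
                 kd_target_genes = as.character(kd_target_genes),
                 effect_genes = effect_genes,
                 mito_gene_fraction = mito_gene_fraction,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 dispersion = dispersion, dropout_shape = dropout_shape,
                 kd_mode = kd_mode, kd_log2fc = kd_log2fc,
                 target_cp10k = target_cp10k, effect_cp10k = effect_cp10k,
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

# simulate one sample's gene x cell count matrix
.sim_sc_sample <- function(cf, n_cells, silenced_fraction, sample_label,
                           genes, rel, target_idx, effect_idx, effect_lfc,
                           seed) {
  set.seed(seed)
  barcodes <- sprintf("%s-%05d", sample_label, seq_len(n_cells))
  silenced <- stats::rbinom(n_cells, 1L, silenced_fraction) == 1L
  depth <- cf$mean_depth * stats::rlnorm(n_cells, -cf$depth_sdlog^2 / 2, cf$depth_sdlog)

  mu <- outer(rel, depth)                      # genes x cells expected counts
  if (length(effect_idx) && any(silenced))
    mu[effect_idx, silenced] <- mu[effect_idx, silenced, drop = FALSE] * 2^effect_lfc
  if (any(silenced)) {
    if (cf$kd_mode == "zero") {
      mu[target_idx, silenced] <- 0
    } else {
      mu[target_idx, silenced] <- mu[target_idx, silenced, drop = FALSE] / 2^cf$kd_log2fc
    }
  }
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / cf$dispersion, mu = mu),
                   nrow(mu), ncol(mu))
  if (!is.null(cf$dropout_shape)) {
    gm <- rowMeans(mu)
    pdet <- stats::plogis(cf$dropout_shape$intercept +
                          cf$dropout_shape$slope * log(pmax(gm, 1e-8)))
    keep <- matrix(stats::rbinom(length(counts), 1L, rep(pdet, ncol(counts))),
                   nrow(counts), ncol(counts))
    counts <- counts * keep
  }
  if (cf$kd_mode == "zero" && any(silenced)) counts[target_idx, silenced] <- 0L
  dimnames(counts) <- list(genes, barcodes)
  list(counts = counts, silenced = barcodes[silenced])
}

#' Simulate a two-sample (Scr, TKD) single-cell knockdown experiment
#'
#' Each cell is drawn silenced with its sample's silenced fraction; silenced
#' cells have all three knockdown targets forced to zero (default mode) and
#' any `effect_genes` shifted by their log2FC. Counts are negative binomial
#' with log-normal per-cell depth; an optional logistic dropout thins
#' detection as a function of mean expression. Mitochondrial genes carry the
#' `"MT-"` name prefix. Deterministic given `config$seed` (the two samples
#' use independent derived sub-seeds).
#'
#' @param config an [sc_sim_config()].
#' @return list with `experiment` (an [sc_experiment()]; both samples
#'   concatenated, labels in `sample_of`) and `truth` (class
#'   `synthetic_truth` with `de_genes`, `silenced_cells`, `sim_config`).
#' @export
generate_sc <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  cf <- config
  n_mito <- round(cf$mito_gene_fraction * cf$n_genes)
  # Th1/Th17 markers used by the joint-state classifier are part of the
  # emulated universe whenever it is large enough to hold them
  markers <- if (cf$n_genes - 3L - n_mito >= 10L) c("TBX21", "RORA") else character(0)
  n_other <- cf$n_genes - 3L - n_mito - length(markers)
  if (n_other < 0) halt("n_genes too small for 3 targets plus mito block")
  genes <- c(cf$kd_target_genes,
             if (n_mito > 0) sprintf("MT-G%03d", seq_len(n_mito)),
             markers,
             sprintf("GENE%05d", seq_len(n_other)))

  if (!is.null(cf$effect_genes)) {
    bad <- setdiff(names(cf$effect_genes), genes)
    if (length(bad)) halt("effect gene(s) not in universe: %s", paste(bad, collapse = ", "))
  }

  seeds <- derive_seeds(cf$seed, 3L)
  set.seed(seeds[1])
  base <- stats::rlnorm(cf$n_genes, log(1), 1.2)
  rel <- base / sum(base)               # relative expression per unit depth
  effect_idx <- integer(0); effect_lfc <- numeric(0)
  if (!is.null(cf$effect_genes)) {
    effect_idx <- match(names(cf$effect_genes), genes)
    effect_lfc <- unname(cf$effect_genes)
  }
  # pin kd targets (and, optionally, planted-effect genes) at defined,
  # well-detected baseline levels; the rest share the remaining mass
  target_idx <- seq_len(3L)
  pinned <- target_idx
  rel[target_idx] <- cf$target_cp10k / 1e4
  if (length(effect_idx) && !is.null(cf$effect_cp10k)) {
    rel[effect_idx] <- cf$effect_cp10k / 1e4
    pinned <- c(pinned, effect_idx)
  }
  free <- setdiff(seq_along(rel), pinned)
  rel[free] <- rel[free] / sum(rel[free]) * (1 - sum(rel[pinned]))

  scr <- .sim_sc_sample(cf, cf$n_cells_scr, cf$silenced_fraction_scr, "Scr",
                        genes, rel, target_idx, effect_idx, effect_lfc, seeds[2])
  tkd <- .sim_sc_sample(cf, cf$n_cells_tkd, cf$silenced_fraction_tkd, "TKD",
                        genes, rel, target_idx, effect_idx, effect_lfc, seeds[3])

  counts <- Matrix::Matrix(cbind(scr$counts, tkd$counts), sparse = TRUE)
  features <- data.frame(gene_id = genes, gene_name = genes,
                         stringsAsFactors = FALSE)
  exper <- sc_experiment(counts, features,
                         sample_of = c(rep("Scr", cf$n_cells_scr),
                                       rep("TKD", cf$n_cells_tkd)))
  truth <- structure(list(de_genes = cf$effect_genes,
                          silenced_cells = c(scr$silenced, tkd$silenced),
                          sim_config = cf),
                     class = "synthetic_truth")
  list(experiment = exper, truth = truth)
}
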