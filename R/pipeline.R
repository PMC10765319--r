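# End-to-end driver: bulk DE per timepoint, single-cell classification
# and downsampling DE, cross-modality overlap, all results written as
# plain-text tables. Fully deterministic given the seeds carried in the
# input configs.

#' Run the full knockdown analysis and write result tables
#'
#' Runs the paired bulk test at every timepoint of the bulk experiment,
#' selects DE genes (FDR < `fdr_max`, FC > `fc_min`), intersects
#' timepoints by direction; on the single-cell side applies QC,
#' log-normalizes, classifies PIM- cells, and runs the
#' downsampling-balanced DE of case PIM- (TKD) cells versus all control
#' (Scr) cells; finally overlaps the bulk and single-cell selections.
#' All tables are written as TSV under `outdir`, and a `summary.json`
#' with the headline counts.
#'
#' @param bulk a [bulk_experiment()].
#' @param sc an [sc_experiment()].
#' @param outdir output directory.
#' @param rots a [rots_config()].
#' @param ds a [downsample_de_config()].
#' @param panel a [marker_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param fdr_max,fc_min bulk selection thresholds.
#' @param signif_prop_min single-cell call threshold on signif_prop.
#' @return invisibly, a list with the in-memory results (`bulk_tables`,
#'   `bulk_sets`, `common`, `qc_report`, `pim_fractions`, `sc_table`,
#'   `sc_set`, `overlap`, `summary`).
#' @export
run_knockdown_pipeline <- function(bulk, sc, outdir,
                                   rots = rots_config(),
                                   ds = downsample_de_config(),
                                   panel = marker_panel(),
                                   thresholds = qc_thresholds(),
                                   fdr_max = 0.1, fc_min = 1.4,
                                   signif_prop_min = 0.95) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  factors <- compute_tmm_factors(bulk)
  tps <- unique(bulk$samples$timepoint)
  bulk_tables <- list(); bulk_sets <- list()
  for (tp in tps) {
    tab <- paired_rots_test(bulk, factors, rots, timepoint = tp)
    bulk_tables[[tp]] <- tab
    bulk_sets[[tp]] <- select_de(tab, fdr_max = fdr_max, fc_min = fc_min)
    tsv(tab, sprintf("bulk_de_%s.tsv", tp))
    tsv(bulk_sets[[tp]], sprintf("bulk_selected_%s.tsv", tp))
  }
  common <- if (length(tps) >= 2)
    common_direction_genes(bulk_sets[[1]], bulk_sets[[2]]) else NULL
  if (!is.null(common)) tsv(common, "bulk_common_direction.tsv")

  qc <- qc_filter(sc, thresholds)
  expr <- log_normalize(qc$experiment)
  cls <- classify_pim_negative(qc$experiment, panel)
  states <- joint_marker_state(qc$experiment, panel)
  tsv(data.frame(barcode = qc$experiment$barcodes,
                 sample = qc$experiment$sample_of,
                 pim_negative = unname(cls$is_negative),
                 joint_state = unname(states)),
      "sc_classification.tsv")
  tsv(cls$fractions, "sc_pim_fractions.tsv")

  case <- qc$experiment$barcodes[qc$experiment$sample_of == "TKD" & cls$is_negative]
  ctrl <- qc$experiment$barcodes[qc$experiment$sample_of == "Scr"]
  sc_tab <- downsample_balanced_de(case, ctrl, expr, ds)
  tsv(sc_tab, "sc_de.tsv")
  sc_set <- call_de_genes(sc_tab, signif_prop_min)
  tsv(sc_set, "sc_selected.tsv")

  ov <- if (!is.null(common)) overlap_de(common, sc_set)
        else overlap_de(bulk_sets[[1]], sc_set)

  summary <- list(n_de_per_timepoint = lapply(bulk_sets, nrow),
                  n_common_same_direction = if (is.null(common)) NA else nrow(common),
                  pim_negative_fractions = stats::setNames(cls$fractions$fraction,
                                                           cls$fractions$sample),
                  n_sc_de = nrow(sc_set),
                  n_bulk_sc_overlap = unname(ov$counts["overlap"]),
                  n_bulk_sc_concordant = unname(ov$counts["concordant"]))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(outdir, "summary.json"))
  }
  invisible(list(bulk_tables = bulk_tables, bulk_sets = bulk_sets,
                 common = common, qc_report = qc$report,
                 pim_fractions = cls$fractions, sc_table = sc_tab,
                 sc_set = sc_set, overlap = ov, summary = summary))
}
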