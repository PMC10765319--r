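# Marker-based cell classification: the operational knockdown-success
# label (PIM-: zero raw counts for all three PIM genes) and joint
# positive/negative states over a marker panel.

#' Marker panel for knockdown and co-expression states
#'
#' @param kd_targets exactly 3 gene names jointly silenced (the PIM
#'   triplet).
#' @param copositives ordered marker names used for joint states
#'   (e.g. `c("TBX21", "RORA")`).
#' @return a `marker_panel` list.
#' @export
marker_panel <- function(kd_targets = c("PIM1", "PIM2", "PIM3"),
                         copositives = c("TBX21", "RORA")) {
  if (length(kd_targets) != 3L) halt("kd_targets must have exactly 3 entries")
  structure(list(kd_targets = as.character(kd_targets),
                 copositives = as.character(copositives)),
            class = "marker_panel")
}

# rows of the count matrix for the given gene names, by gene_name
.marker_rows <- function(experiment, genes) {
  idx <- match(genes, experiment$features$gene_name)
  if (anyNA(idx))
    halt("marker gene(s) not found: %s", paste(genes[is.na(idx)], collapse = ", "))
  idx
}

#' Classify knockdown-negative (PIM-) cells
#'
#' A cell is PIM- iff its raw count is exactly zero for all three
#' knockdown targets. Operates on post-QC raw counts ("undetectable"
#' means no UMI observed).
#'
#' @param experiment an [sc_experiment()] (QC-filtered).
#' @param panel a [marker_panel()].
#' @return list with `is_negative` (named logical per barcode) and
#'   `fractions` (data.frame `sample`, `n_cells`, `n_negative`,
#'   `fraction`).
#' @export
classify_pim_negative <- function(experiment, panel = marker_panel()) {
  stopifnot(inherits(experiment, "SCExperiment"), inherits(panel, "marker_panel"))
  idx <- .marker_rows(experiment, panel$kd_targets)
  sub <- experiment$counts[idx, , drop = FALSE]
  neg <- Matrix::colSums(sub > 0) == 0
  names(neg) <- experiment$barcodes
  tab <- tapply(neg, experiment$sample_of, function(v) c(n = length(v), k = sum(v)))
  fractions <- data.frame(sample = names(tab),
                          n_cells = vapply(tab, `[[`, 0, 1),
                          n_negative = vapply(tab, `[[`, 0, 2),
                          stringsAsFactors = FALSE, row.names = NULL)
  fractions$fraction <- fractions$n_negative / fractions$n_cells
  list(is_negative = neg, fractions = fractions)
}

#' Joint marker state of each cell
#'
#' Collapses the three knockdown targets into one PIM group (positive iff
#' any target has a nonzero count) and tags each co-marker positive iff its
#' count is nonzero, yielding state strings such as `"PIM-/TBX21-/RORA+"`.
#'
#' @param experiment an [sc_experiment()].
#' @param panel a [marker_panel()].
#' @return named character vector of state strings, one per cell.
#' @export
joint_marker_state <- function(experiment, panel = marker_panel()) {
  stopifnot(inherits(experiment, "SCExperiment"), inherits(panel, "marker_panel"))
  t_idx <- .marker_rows(experiment, panel$kd_targets)
  pim_pos <- Matrix::colSums(experiment$counts[t_idx, , drop = FALSE] > 0) > 0
  parts <- list(paste0("PIM", ifelse(pim_pos, "+", "-")))
  for (mk in panel$copositives) {
    i <- .marker_rows(experiment, mk)
    pos <- as.vector(experiment$counts[i, ] > 0)
    parts[[length(parts) + 1L]] <- paste0(mk, ifelse(pos, "+", "-"))
  }
  states <- do.call(paste, c(parts, sep = "/"))
  stats::setNames(states, experiment$barcodes)
}
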