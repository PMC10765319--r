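# Cross-modality concordance of DE gene sets, plus the small assay
# quantification formulas: ddCt relative qPCR quantification and
# live-cell-normalized readouts anchored to the control condition.

#' Overlap two signed DE gene sets
#'
#' Intersects the bulk and single-cell selections (or any two signed
#' sets) and splits the overlap by direction agreement. Symmetric in its
#' arguments for the overlap; `concordant` and `discordant` partition it.
#'
#' @param set_a,set_b [signed_gene_set()]s.
#' @return list with `overlap`, `concordant`, `discordant` (signed sets;
#'   directions taken from `set_a`) and `counts` (named integer vector).
#' @export
overlap_de <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "signed_gene_set"), inherits(set_b, "signed_gene_set"))
  common <- intersect(set_a$gene, set_b$gene)
  da <- set_a$direction[match(common, set_a$gene)]
  db <- set_b$direction[match(common, set_b$gene)]
  prov <- paste(attr(set_a, "provenance"), attr(set_b, "provenance"), sep = "&")
  agree <- da == db
  list(overlap = signed_gene_set(common, da, prov),
       concordant = signed_gene_set(common[agree], da[agree], prov),
       discordant = signed_gene_set(common[!agree], da[!agree], prov),
       counts = c(overlap = length(common),
                  concordant = sum(agree),
                  discordant = sum(!agree)))
}

#' A qPCR cycle-threshold record
#'
#' Technical replicates are averaged on the Ct scale before any delta is
#' formed.
#'
#' @param ct_target Ct value(s) of the gene of interest.
#' @param ct_reference Ct value(s) of the endogenous control (EF1a-type
#'   reference).
#' @param condition condition label.
#' @return a `ct_record` list with scalar `ct_target`, `ct_reference`.
#' @export
ct_record <- function(ct_target, ct_reference, condition = NA_character_) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    halt("Ct values must be finite")
  structure(list(ct_target = mean(ct_target),
                 ct_reference = mean(ct_reference),
                 condition = condition),
            class = "ct_record")
}

#' Relative expression fold change by the ddCt method
#'
#' `dCt = Ct(target) - Ct(reference)` per condition;
#' `ddCt = dCt(case) - dCt(control)`; fold change `= 2^(-ddCt)`
#' (amplification efficiency fixed at 2).
#'
#' @param case,control [ct_record()]s.
#' @return the linear fold change of case relative to control.
#' @export
ddct_fold_change <- function(case, control) {
  stopifnot(inherits(case, "ct_record"), inherits(control, "ct_record"))
  dct_case <- case$ct_target - case$ct_reference
  dct_ctrl <- control$ct_target - control$ct_reference
  2^(-(dct_case - dct_ctrl))
}

#' Normalize assay readouts for live-cell count, anchored to a control
#'
#' Each sample's readout (e.g. secreted cytokine by ELISA) is divided by
#' its live-cell count, then expressed relative to the control sample's
#' per-cell value, so the control maps exactly to 1.
#'
#' @param values named numeric vector of raw readouts.
#' @param live_counts named numeric vector of live-cell counts (same
#'   names, all positive).
#' @param control_label name of the control sample (e.g. `"Scr"`).
#' @return named numeric vector of normalized readouts.
#' @export
normalize_readout <- function(values, live_counts, control_label) {
  if (is.null(names(values)) || is.null(names(live_counts)))
    halt("values and live_counts must be named by sample")
  if (!setequal(names(values), names(live_counts)))
    halt("values and live_counts name sets differ")
  live_counts <- live_counts[names(values)]
  if (any(live_counts <= 0)) halt("live counts must be positive")
  if (!control_label %in% names(values))
    halt("control sample '%s' missing", control_label)
  per_cell <- values / live_counts
  per_cell / per_cell[[control_label]]
}
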