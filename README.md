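# pimtkd

Differential-expression analysis for PIM triple-knockdown (TKD) Th17
transcriptomics — the computational chain for studying what simultaneous
silencing of the kinases PIM1, PIM2 and PIM3 does to differentiating
human Th17 cells, on two modalities:

* **Paired bulk RNA-seq** (donor pairs of TKD vs scrambled control, two
  timepoints): TMM normalization, a *paired reproducibility-optimized
  resampling test*, selection at FDR < 0.1 and fold change > 1.4, and
  the same-direction intersection across timepoints.
* **Single-cell RNA-seq** (one TKD and one Scr sample): QC (>10%
  mitochondrial or <200 detected genes removed), CP10K `log1p`
  normalization, classification of knockdown-negative (**PIM⁻**) cells —
  zero raw counts for all three PIM genes — and a
  *downsampling-balanced Wilcoxon DE*: the control group is downsampled
  100× to the case size, each subset tested per gene (Wilcoxon
  rank-sum, BH correction), and results aggregated as **signif_prop**,
  the proportion of subsets with FDR < 0.05 and |log2FC| > 0.24.
* **Integration and assay utilities**: direction-aware overlap of bulk
  and single-cell gene sets, ddCt qPCR fold changes
  (FC = 2^(−ΔΔCt)), live-cell-normalized secretion readouts.
* **Synthetic data with ground truth**: negative-binomial generators
  for both modalities (paired donor effects, planted log2FCs,
  knockdown-silenced cells at configurable fractions, logistic
  dropout), so calibration and power of every stage are testable.

The bulk test statistic family is d = |m| / (α₁ + α₂·s), where m is the
mean per-pair log2-cpm difference and s its standard error; (α₁, α₂) and
a top-list size k are chosen to maximize Z = (R − R⁰)/sd(R), the
bootstrap top-k-overlap reproducibility R against its sign-flip null
R⁰. FDR comes from sign-flip permutations of the selected statistic.
See the methods vignette (`vignettes/knockdown-transcriptomics.Rmd`)
for formulas, defaults and design rationale.

## Worked example

```r
library(pimtkd)

bulk <- generate_bulk(bulk_sim_config(n_genes = 500, seed = 51))$experiment
sc   <- generate_sc(sc_sim_config(n_genes = 400, n_cells_scr = 400,
                                  n_cells_tkd = 250,
                                  effect_genes = c(GENE00001 = 1.5,
                                                   GENE00002 = -1.5),
                                  seed = 52))$experiment

res <- run_knockdown_pipeline(bulk, sc, "results_demo",
  rots = rots_config(B = 200, n_perm = 200, seed = 53),
  ds = downsample_de_config(n_subsets = 50, seed = 54),
  thresholds = qc_thresholds(min_genes_detected = 150))

res$pim_fractions
#>   sample n_cells n_negative fraction
#> 1    Scr     400        102    0.255
#> 2    TKD     250        129    0.516

head(res$sc_table[order(-res$sc_table$signif_prop),
                  c("gene", "mean_log2fc", "signif_prop")], 5)
#>         gene mean_log2fc signif_prop
#> 1       PIM1  -2.9602053           1
#> 2       PIM2  -3.0454092           1
#> 3       PIM3  -3.0337206           1
#> 26 GENE00001   0.9675794           1
#> 27 GENE00002  -0.9271396           1
```

The PIM⁻ fractions recover the simulated silencing rates (0.26 Scr,
0.53 TKD); the single-cell DE ranks the three silenced PIM genes as the
strongest down-regulated genes in PIM⁻ cells and recovers both planted
effects with the correct sign in every downsampled subset
(signif_prop = 1). Result tables (per-timepoint bulk DE, selections,
per-cell classification, downsampling DE, summary JSON) are written to
the output directory and are byte-identical across reruns with the same
seeds.

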