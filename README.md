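# regulonforge

Signed transcription-factor regulon inference and validation for
single-cell and bulk count data.

## The problem

When a transcription factor (TF) patterns a progenitor population — a
graded regulator in nascent mesoderm, say — its direct output is a pair of
*regulons*: the set of genes it activates and the set it represses.
Recovering those signed target sets from data requires stitching together
several lines of evidence, each individually noisy:

* **Perturbation**: expression change in a knockout versus wild type;
* **Dose response**: expression change between cells with high and low TF
  expression within the same population;
* **Binding**: a ChIP peak for the TF near the gene's transcription start
  site (TSS);
* **Kinetics**: whether the gene responds within hours of acute TF
  induction, marking it as a probable early (direct) target;
* **Network stability**: whether stochastic co-expression network
  inference finds the TF→gene edge reproducibly across reruns.

`regulonforge` implements this whole evidence chain as composable,
testable R functions, and ships a synthetic-data generator with planted
ground truth so every stage — and the pipeline end to end — can be
validated against known answers.

## What is in the box

* **Dual-contrast target calling** (`run_target_pipeline()` and its
  parts): genes significant in *both* the KO-vs-WT and TF-high-vs-TF-low
  contrasts (FDR < 0.05), with concordant signs (activated = down in KO,
  up in TF-high; repressed = the mirror image), then filtered to genes
  with a binding region within 100 kb of the TSS (inclusive).
* **Exact NB differential test** (`nb_test()`): a two-sided exact-style
  test conditional on the normalized two-group total under a
  negative-binomial model (variance = μ + φμ²), with method-of-moments
  dispersions shrunk toward a common Stein-type target
  (`shrunk_dispersions()`), median-of-ratios size factors
  (`size_factors()`), and Benjamini–Hochberg correction (`adjust_fdr()`).
* **Consensus regulons** (`run_consensus_grn()`): seeded tree-ensemble
  TF→target importances (`score_adjacencies()`), motif-support pruning of
  the top-k targets per TF (`prune_by_motif()`, ±10 kb TSS window), and
  the multi-run stability rule (`consensus_regulons()`): a regulator must
  appear in **all** 5 runs; targets must recur in ≥ 2 runs.
* **Regulon activity and specificity** (`score_regulon_activity()`):
  AUCell-style per-cell scores — the area under the recovery curve of a
  gene set within the top 5% of each cell's ranked expression profile,
  normalized so a fully top-ranked set scores exactly 1 — with automatic
  bimodal activity thresholds, and regulon specificity scores
  `RSS = 1 − sqrt(JSD₂(P, Q))` per cell type with 95th-percentile
  flagging (`regulon_specificity()`).
* **Early-target flagging** (`flag_early_targets()`): calls against a
  3-replicate short-induction bulk experiment after subtracting genes
  that respond to the inducer alone in a control line
  (`subtract_confounder_responders()`).
* **Motif enrichment** (`enrich_classes()`): class-unique open-chromatin
  regions (`class_unique_regions()`), equal-size random down-sampling
  (`downsample_equal()`), and an exact upper-tail binomial statistic
  against background with the `p < 1e-6` significance convention.
* **Interval utilities**: 200-bp summit-centred windows, merging,
  replicated-peak support, TSS distances — all in 0-based half-open (BED)
  coordinates, with BED/narrowPeak/GTF/GMT/MTX readers and writers.
* **A synthetic study generator** (`sim_config()`, `generate_truth()`,
  `simulate_cells()`, `simulate_peaks()`, `simulate_induction_bulk()`,
  `mad_filter_cells()`): NB counts under a graded regulator in wild-type
  mesoderm, a knockout population with the TF ablated, summit-centred
  peaks placed (or decoyed) relative to true-target TSSs, planted
  induction responders and dox confounders, and MAD-based cell QC.

## Worked example

A reduced study — 800 genes with 80 planted activated and 80 repressed
targets, 600 wild-type and 600 knockout mesoderm cells — run end to end:

```r
library(regulonforge)

cfg <- sim_config(n_genes = 800, n_activated = 80, n_repressed = 80,
                  cell_groups = data.frame(genotype = c("WT", "KO"),
                                           cell_type = "mesoderm",
                                           n = c(600, 600)),
                  decoy_peak_count = 100)
res <- run_target_pipeline(cfg, seed = 1)

res$regulons$activating
#> <regulon> TF1(+): 69 targets [custom_dual_contrast]
res$regulons$repressing
#> <regulon> TF1(-): 58 targets [custom_dual_contrast]
str(res$metrics)
#> List of 2
#>  $ activating: Named num [1:3] 0.863 1 69
#>   ..- attr(*, "names")= chr [1:3] "sensitivity" "precision" "n_called"
#>  $ repressing: Named num [1:3] 0.725 1 58
#>   ..- attr(*, "names")= chr [1:3] "sensitivity" "precision" "n_called"
round(res$early$fractions, 3)
#> activating repressing
#>      0.507      0.500
```

Reading: of the 80 planted activated targets the dual-contrast +
binding-filter pipeline recovered 69 (sensitivity 0.86) with no false
positives (precision 1.0); repression is intrinsically harder to detect
at these cell numbers (0.73, rising to ≈ 0.87 at the default 2,000 + 2,000
cells). About half of each called regulon is flagged as early-responding
in the 12 h induction contrast — matching the planted fraction of 0.5.

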