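#' Stratify cells by TF expression quantiles
#'
#' Splits a population into TF-high (top quantile) and TF-low (bottom
#' quantile) strata on size-factor-normalized TF expression. Ties at the
#' cut are resolved by a seeded random order so each stratum has exactly
#' `floor(q * n)` cells.
#'
#' @param expr A `cell_matrix` (already restricted to the population of
#'   interest, e.g. mesoderm) or a counts matrix.
#' @param tf TF gene id (must be a row of the matrix).
#' @param q Quantile size; default 0.25 (quartiles).
#' @param seed Seed for tie-breaking.
#' @param size_factors Optional per-cell factors; computed when `NULL`.
#' @param population Optional label recorded in the result.
#' @return A `stratified_cells` list: `high`, `low` (cell id vectors),
#'   `q`, `population`.
#' @export
stratify_by_tf <- function(expr, tf, q = 0.25, seed = 1,
                           size_factors = NULL, population = NA_character_) {
  counts <- if (inherits(expr, "cell_matrix")) expr$counts else as.matrix(expr)
  if (!tf %in% rownames(counts)) stop2("TF '", tf, "' not in the matrix")
  n <- ncol(counts)
  k <- floor(q * n)
  if (k < 1) stop2("population too small for quantile ", q)
  if (is.null(size_factors)) size_factors <- size_factors(counts)
  x <- counts[tf, ] / size_factors
  if (quantile(x, q) == quantile(x, 1 - q))
    stop2("strata indistinguishable: degenerate TF quantiles")
  ord <- with_seed(seed, order(x, runif(n)))
  cells <- colnames(counts)
  structure(list(low = sort(cells[ord[seq_len(k)]]),
                 high = sort(cells[ord[(n - k + 1):n]]),
                 q = q, population = population),
            class = "stratified_cells")
}

#' Concordant signed target candidates from two contrasts
#'
#' Combines the knockout-vs-wild-type and TF-high-vs-TF-low contrasts:
#' activated candidates are significant in both, down in KO vs WT and up
#' in high vs low; repressed candidates the mirror image. Fold changes are
#' read as level-2-over-level-1 of each table's contrast
#' (`de_ko_vs_wt`: KO over WT; `de_high_vs_low`: high over low).
#'
#' @param de_ko_vs_wt,de_high_vs_low `de_table`s over a shared gene
#'   universe.
#' @param alpha FDR threshold applied to both contrasts.
#' @return List with character vectors `activated` and `repressed`.
#' @export
concordant_targets <- function(de_ko_vs_wt, de_high_vs_low, alpha = 0.05) {
  shared <- intersect(de_ko_vs_wt$unit_id, de_high_vs_low$unit_id)
  ko <- de_ko_vs_wt[match(shared, de_ko_vs_wt$unit_id), ]
  hl <- de_high_vs_low[match(shared, de_high_vs_low$unit_id), ]
  sig <- ko$q < alpha & hl$q < alpha
  activated <- shared[sig & ko$log2_fc < 0 & hl$log2_fc > 0]
  repressed <- shared[sig & ko$log2_fc > 0 & hl$log2_fc < 0]
  list(activated = sort(activated), repressed = sort(repressed))
}

#' Filter candidates by TF binding near the TSS
#'
#' Retains candidates whose minimum peak-to-TSS distance over all binding
#' regions is within the window (inclusive: "within 100 kb" read as <=),
#' and packages the survivors as an activating and a repressing regulon
#' with provenance `custom_dual_contrast`.
#'
#' @param candidates List with `activated` and `repressed` gene id
#'   vectors (from [concordant_targets()]).
#' @param peaks A [region_set()] of binding regions.
#' @param annotation A [gene_annotation()].
#' @param window Proximity window in bp; default 100000.
#' @param tf TF id recorded on the returned regulons.
#' @return List with `activating`/`repressing` regulons (`NULL` when
#'   empty), and `calls`, a per-gene table with direction and minimum
#'   TSS-peak distance.
#' @export
filter_by_binding <- function(candidates, peaks, annotation,
                              window = 100000, tf = "TF") {
  if (window <= 0) stop2("`window` must be > 0")
  genes <- c(candidates$activated, candidates$repressed)
  direction <- rep(c("activated", "repressed"),
                   c(length(candidates$activated),
                     length(candidates$repressed)))
  ann <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  if (any(is.na(ann$gene_id))) stop2("candidate gene missing from annotation")
  d <- if (nrow(peaks) == 0) rep(Inf, length(genes)) else
    min_peak_distance(ann, peaks)
  keep <- d <= window
  calls <- data.frame(gene = genes, direction = direction,
                      min_tss_distance = unname(d), retained = keep,
                      stringsAsFactors = FALSE)
  mk <- function(dirn, mode) {
    t <- genes[keep & direction == dirn]
    if (length(t) == 0) return(NULL)
    regulon(tf, mode, t, provenance = "custom_dual_contrast")
  }
  list(activating = mk("activated", "activating"),
       repressing = mk("repressed", "repressing"),
       calls = calls, window = window)
}

#' Remove genes responding to the inducer alone
#'
#' Drops from an induction DE table every gene significant in the
#' control-line contrast (a line without the transgene, exposed to the
#' same inducer), so that inducer-driven responses cannot masquerade as TF
#' responses.
#'
#' @param de_induced `de_table` of the transgene induction contrast.
#' @param de_confounder_control_line `de_table` of the control-line
#'   contrast over the same genes.
#' @param alpha FDR threshold for calling a confounder gene.
#' @return The filtered `de_table`; removed ids in
#'   `attr(, "confounder_removed")`.
#' @export
subtract_confounder_responders <- function(de_induced,
                                           de_confounder_control_line,
                                           alpha = 0.05) {
  conf <- de_confounder_control_line$unit_id[
    de_confounder_control_line$q < alpha]
  out <- de_induced[!de_induced$unit_id %in% conf, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(de_induced)
  attr(out, "confounder_removed") <- sort(intersect(conf,
                                                    de_induced$unit_id))
  out
}

#' Flag probable early targets against a short-induction contrast
#'
#' A called target is an early target when it is significant in the
#' (confounder-subtracted) induction contrast with the direction matching
#' its mode: activated targets up on induction, repressed targets down.
#' Also reports the per-mode concordant fractions.
#'
#' @param regulons List with `activating` and/or `repressing` regulons
#'   (as from [filter_by_binding()]).
#' @param de_induction `de_table` of induced vs control, already
#'   confounder-subtracted.
#' @param alpha FDR threshold.
#' @return List with `early` (named list of early-target vectors per mode)
#'   and `fractions` (named numeric, concordant fraction per mode).
#' @export
flag_early_targets <- function(regulons, de_induction, alpha = 0.05) {
  de <- de_induction
  flag_mode <- function(reg, up) {
    if (is.null(reg)) return(NULL)
    m <- de[match(reg$targets, de$unit_id), , drop = FALSE]
    hit <- !is.na(m$q) & m$q < alpha &
      (if (up) m$log2_fc > 0 else m$log2_fc < 0)
    reg$targets[hit]
  }
  early <- list(activating = flag_mode(regulons$activating, up = TRUE),
                repressing = flag_mode(regulons$repressing, up = FALSE))
  frac <- vapply(c("activating", "repressing"), function(mode) {
    reg <- regulons[[mode]]
    if (is.null(reg) || length(reg$targets) == 0) return(NA_real_)
    length(early[[mode]]) / length(reg$targets)
  }, numeric(1))
  list(early = early, fractions = frac)
}

#' Overexpression-derived custom regulon
#'
#' Targets upregulated on TF induction (an FDR and fold-change filtered
#' up-set) intersected with the TF's co-expression adjacencies, enriching
#' for direct targets; mode is activating, provenance
#' `custom_overexpression`.
#'
#' @param de_up Character vector of upregulated gene ids (e.g. the `up`
#'   element of [de_with_fc_filter()]).
#' @param adjacencies An `adjacency` data frame containing the TF.
#' @param tf TF gene id.
#' @return A `regulon`, or `NULL` when the intersection is empty.
#' @export
overexpression_regulon <- function(de_up, adjacencies, tf) {
  if (!tf %in% adjacencies$tf) stop2("adjacencies do not contain TF '",
                                     tf, "'")
  adj_targets <- adjacencies$target[adjacencies$tf == tf &
                                      adjacencies$importance > 0]
  t <- intersect(de_up, adj_targets)
  if (length(t) == 0) return(NULL)
  regulon(tf, "activating", t, provenance = "custom_overexpression")
}
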