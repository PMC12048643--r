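#' Motif hit tables
#'
#' Boolean per-(motif, region) hits plus a background hit frequency per
#' motif. Any (motif, region) pair is queryable; pairs not listed are
#' misses.
#'
#' @param hits Data frame with columns `motif_id` and `region_id` (one row
#'   per hit).
#' @param p_bg Named numeric vector of background hit frequencies in
#'   `(0, 1)`, one per motif.
#' @return A `motif_hit_table`.
#' @export
motif_hit_table <- function(hits, p_bg) {
  if (any(p_bg <= 0 | p_bg >= 1)) stop2("p_bg must lie in (0, 1)")
  if (is.null(names(p_bg))) stop2("`p_bg` must be named by motif")
  structure(list(keys = unique(paste(hits$motif_id, hits$region_id,
                                     sep = "\r")),
                 p_bg = p_bg, motifs = names(p_bg)),
            class = "motif_hit_table")
}

#' @rdname motif_hit_table
#' @param x A `motif_hit_table`.
#' @param motif_id Single motif id.
#' @param region_ids Region ids to query.
#' @return `has_hit()`: logical vector over `region_ids`.
#' @export
has_hit <- function(x, motif_id, region_ids) {
  paste(motif_id, region_ids, sep = "\r") %in% x$keys
}

#' @rdname motif_hit_table
#' @param path TSV with columns motif_id, region_id; background rates come
#'   from a two-column header-less sidecar or the `p_bg` argument.
#' @export
read_motif_hits <- function(path, p_bg) {
  hits <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  motif_hit_table(hits, p_bg)
}

#' Down-sample labelled region sets to a common size
#'
#' Reduces every peak set to the same number of regions by seeded random
#' sampling without replacement, so binomial significance values are
#' comparable across classes.
#'
#' @param sets Named list of [region_set()]s.
#' @param n Target size; defaults to the smallest set size.
#' @param seed Integer seed.
#' @return Named list of [region_set()]s, each with exactly `n` rows.
#' @export
downsample_equal <- function(sets, n = NULL, seed = 1) {
  sizes <- vapply(sets, nrow, numeric(1))
  if (is.null(n)) n <- min(sizes)
  short <- names(sets)[sizes < n]
  if (length(short))
    stop2("set(s) smaller than n = ", n, ": ",
          paste(short, collapse = ", "))
  with_seed(seed, {
    lapply(sets, function(s)
      as_region_set(s[sort(sample(nrow(s), n)), , drop = FALSE]))
  })
}

#' Exact binomial enrichment p-value
#'
#' Upper-tail exact binomial probability `P(X >= k | n, p_bg)`, computed
#' in log space so the deep-tail regime behind a `p < 1e-6` significance
#' convention remains accurate.
#'
#' @param k Observed regions with a hit (`0 <= k <= n`).
#' @param n Regions tested.
#' @param p_bg Background hit frequency in `(0, 1)`.
#' @return The upper-tail p-value.
#' @export
binomial_enrichment <- function(k, n, p_bg) {
  if (any(p_bg <= 0 | p_bg >= 1)) stop2("p_bg must lie in (0, 1)")
  if (any(k < 0 | k > n)) stop2("k must lie in [0, n]")
  ifelse(k == 0, 1, pbinom(k - 1, n, p_bg, lower.tail = FALSE))
}

#' Motif enrichment over equal-sized class-unique region sets
#'
#' For each motif and class: `k` regions carrying a hit out of the `n`
#' down-sampled regions, an exact upper-tail binomial p-value against the
#' motif's background rate, significance at the `p < alpha` convention
#' (default 1e-6), and the cross-class mean hit fraction as the
#' background-line analogue reported alongside.
#'
#' @param class_sets Named list of equal-sized [region_set()]s (enforce
#'   with [downsample_equal()]).
#' @param hits A [motif_hit_table()].
#' @param motifs Motif ids to test; default all motifs in `hits`.
#' @param alpha Significance threshold on the p-value.
#' @return An `enrichment_result` data frame: motif_id, class, n, k,
#'   p_bg, p, significant, cross_class_rate.
#' @export
enrich_classes <- function(class_sets, hits, motifs = NULL, alpha = 1e-6) {
  sizes <- vapply(class_sets, nrow, numeric(1))
  if (length(unique(sizes)) != 1)
    stop2("class sets must be equal-sized; run downsample_equal() first")
  if (is.null(motifs)) motifs <- hits$motifs
  n <- sizes[[1]]
  rows <- list()
  for (m in motifs) {
    k <- vapply(class_sets, function(s)
      sum(has_hit(hits, m, s$name)), numeric(1))
    p <- binomial_enrichment(k, n, hits$p_bg[[m]])
    rows[[m]] <- data.frame(motif_id = m, class = names(class_sets),
                            n = n, k = unname(k),
                            p_bg = hits$p_bg[[m]], p = unname(p),
                            significant = unname(p) < alpha,
                            cross_class_rate = mean(k) / n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
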