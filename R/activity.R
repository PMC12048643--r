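#' Per-cell gene rankings
#'
#' Ranks genes within each cell by descending count; ties are broken by a
#' seeded random key fixed per cell, avoiding the systematic bias a
#' stable-by-index tie-break would impose on sparse counts.
#'
#' @param expr A `cell_matrix` or counts matrix (genes x cells).
#' @param seed Integer seed for the tie-break keys.
#' @return Integer matrix of ranks (1 = highest count), genes x cells,
#'   with the seed recorded in `attr(, "seed")`.
#' @export
rank_genes_per_cell <- function(expr, seed = 1) {
  counts <- if (inherits(expr, "cell_matrix")) expr$counts else as.matrix(expr)
  with_seed(seed, {
    G <- nrow(counts)
    ranks <- matrix(0L, nrow = G, ncol = ncol(counts),
                    dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts))) {
      key <- runif(G)
      ord <- order(-counts[, j], key)
      ranks[ord, j] <- seq_len(G)
    }
    attr(ranks, "seed") <- seed
    ranks
  })
}

#' Area-under-recovery-curve score for one ranking
#'
#' With `M = ceiling(top_fraction * G)` and recovery `R(i)` the number of
#' set genes among the top `i` ranks, the score is
#' `sum_{i=1..M} R(i) / sum_{i=1..M} min(i, |set|)` — the recovery-curve
#' area normalized by the maximal achievable area for the set size, so a
#' set entirely inside the window scores 1 and one entirely outside scores
#' 0.
#'
#' @param ranking Either a character vector of genes in rank order or a
#'   named integer rank vector (1 = top).
#' @param gene_set Non-empty character vector; genes absent from the
#'   universe are ignored, but a set fully disjoint from it is an error.
#' @param top_fraction Fraction of the ranking examined, in `(0, 1]`.
#' @return Score in `[0, 1]`.
#' @export
auc_score <- function(ranking, gene_set, top_fraction = 0.05) {
  if (length(gene_set) == 0) stop2("`gene_set` must be non-empty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop2("`top_fraction` must be in (0, 1]")
  if (is.character(ranking)) {
    G <- length(ranking)
    pos <- match(gene_set, ranking)
  } else {
    G <- length(ranking)
    pos <- unname(ranking[match(gene_set, names(ranking))])
  }
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0)
    stop2("`gene_set` is disjoint from the gene universe")
  auc_from_positions(pos, G, top_fraction)
}

auc_from_positions <- function(pos, G, top_fraction) {
  M <- ceiling(top_fraction * G)
  S <- length(pos)
  denom <- sum(pmin(seq_len(M), S))
  num <- sum(M - pos[pos <= M] + 1)
  num / denom
}

#' Score regulon activity across all cells
#'
#' AUCell-style activity: per cell, the area under the recovery curve of
#' each regulon's target set within the top-ranked fraction of the cell's
#' expression profile, plus an automatic per-regulon activity threshold.
#'
#' @param expr A `cell_matrix` or counts matrix.
#' @param regulons A `regulon_set` (or plain named list of gene sets).
#' @param top_fraction Fraction of genes examined per cell.
#' @param seed Seed for the ranking tie-breaks.
#' @return An `activity_matrix` list: `scores` (regulon x cell),
#'   `thresholds`, `top_fraction`, `seed`.
#' @export
score_regulon_activity <- function(expr, regulons, top_fraction = 0.05,
                                   seed = 1) {
  counts <- if (inherits(expr, "cell_matrix")) expr$counts else as.matrix(expr)
  ranks <- rank_genes_per_cell(counts, seed = seed)
  G <- nrow(ranks)
  M <- ceiling(top_fraction * G)
  sets <- lapply(regulons, function(r)
    if (inherits(r, "regulon")) r$targets else r)
  scores <- matrix(0, nrow = length(sets), ncol = ncol(ranks),
                   dimnames = list(names(sets), colnames(ranks)))
  for (k in seq_along(sets)) {
    idx <- match(sets[[k]], rownames(ranks))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0)
      stop2("regulon '", names(sets)[k], "' is disjoint from the universe")
    S <- length(idx)
    denom <- sum(pmin(seq_len(M), S))
    rk <- ranks[idx, , drop = FALSE]
    contrib <- (M - rk + 1) * (rk <= M)
    scores[k, ] <- colSums(contrib) / denom
  }
  structure(list(scores = scores,
                 thresholds = apply(scores, 1, activity_threshold),
                 top_fraction = top_fraction, seed = seed),
            class = "activity_matrix")
}

#' Automatic activity threshold for one regulon
#'
#' Takes the deepest density minimum between the two largest modes of a
#' kernel-density estimate of the score distribution; for unimodal
#' distributions falls back to mean + 2 SD capped at the maximum score.
#' Constant scores return that constant (cells at the threshold count as
#' at-threshold, never "all below").
#'
#' @param scores Numeric vector of per-cell activity scores (>= 10 cells).
#' @return Threshold within `[min(scores), max(scores)]`.
#' @export
activity_threshold <- function(scores) {
  if (length(scores) < 10) stop2("need at least 10 cells")
  rng <- range(scores)
  if (diff(rng) == 0) return(rng[1])
  d <- density(scores)
  y <- d$y; x <- d$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  # boundary modes count too
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  peaks <- which(is_max)
  thr <- if (length(peaks) >= 2) {
    top2 <- peaks[order(-y[peaks])][1:2]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1
    x[valley]
  } else {
    mean(scores) + 2 * sd(scores)
  }
  min(max(thr, rng[1]), rng[2])
}

#' Regulon specificity scores
#'
#' For regulon r and cell type c, `P` is the regulon's activity vector
#' normalized to sum 1 over cells, `Q` the normalized indicator of
#' membership in c, and `RSS = 1 - sqrt(JSD2(P, Q))` with base-2
#' Jensen-Shannon divergence, so a regulon active uniformly on exactly the
#' type's cells scores 1 and one fully outside it scores 0. Values above
#' the `flag_quantile` percentile of the whole table (or per cell type
#' with `per_type = TRUE`) are flagged.
#'
#' @param activity An `activity_matrix` (or a regulon x cell score
#'   matrix).
#' @param cell_labels Cell-type label per cell (>= 2 types).
#' @param flag_quantile Percentile (default 0.95) above which values are
#'   flagged.
#' @param per_type Compute the flagging percentile within each cell type
#'   instead of globally.
#' @return An `rss_table` list: `rss` (regulon x cell type, `NA` rows for
#'   all-zero regulons), `flagged` (logical, same shape), `missing`
#'   (regulons with undefined RSS).
#' @export
regulon_specificity <- function(activity, cell_labels, flag_quantile = 0.95,
                                per_type = FALSE) {
  scores <- if (inherits(activity, "activity_matrix")) activity$scores else
    as.matrix(activity)
  cell_labels <- as.character(cell_labels)
  if (length(cell_labels) != ncol(scores))
    stop2("`cell_labels` must match the number of cells")
  types <- sort(unique(cell_labels))
  if (length(types) < 2) stop2("need at least 2 cell types")
  rss <- matrix(NA_real_, nrow = nrow(scores), ncol = length(types),
                dimnames = list(rownames(scores), types))
  for (r in seq_len(nrow(scores))) {
    tot <- sum(scores[r, ])
    if (tot == 0) next
    P <- scores[r, ] / tot
    for (ti in seq_along(types)) {
      ind <- as.numeric(cell_labels == types[ti])
      Q <- ind / sum(ind)
      jsd <- min(max(js_divergence2(P, Q), 0), 1)   # guard rounding
      rss[r, ti] <- 1 - sqrt(jsd)
    }
  }
  vals <- rss[!is.na(rss)]
  flagged <- matrix(FALSE, nrow(rss), ncol(rss), dimnames = dimnames(rss))
  if (length(vals)) {
    if (per_type) {
      for (ti in seq_len(ncol(rss))) {
        cut <- quantile(rss[, ti], flag_quantile, na.rm = TRUE)
        flagged[, ti] <- !is.na(rss[, ti]) & rss[, ti] > cut
      }
    } else {
      cut <- quantile(vals, flag_quantile)
      flagged <- !is.na(rss) & rss > cut
    }
  }
  structure(list(rss = rss, flagged = flagged,
                 missing = rownames(scores)[rowSums(scores) == 0],
                 flag_quantile = flag_quantile, per_type = per_type),
            class = "rss_table")
}

# Base-2 Jensen-Shannon divergence between probability vectors; bounded in
# [0, 1], 1 exactly for disjoint supports.
js_divergence2 <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / M[i]))
  }
  (kl(P) + kl(Q)) / 2
}
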