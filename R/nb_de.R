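#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across units of
#' the ratio to the per-unit geometric mean, using only units observed in
#' every sample; factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, units (rows) x samples (columns).
#' @return Numeric vector of positive factors, one per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop2("a sample has all-zero counts")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop2("no unit has nonzero counts in every sample; cannot form ratios")
  lc <- log(counts[use, , drop = FALSE])
  sf <- exp(apply(lc - log_geo[use], 2, median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments NB dispersions with Stein-type shrinkage
#'
#' Per-unit raw dispersions are method-of-moments estimates
#' `phi = max(0, (s^2 - mu) / mu^2)` from size-factor-normalized counts,
#' with `s^2` the within-group pooled variance and `mu` the overall mean.
#' Raw estimates are shrunk toward a common target `xi` (the grid point
#' minimizing the mean squared distance to the raw estimates) with weight
#' `delta = min(1, sum(Var(phi_hat)) / sum((phi_hat - xi)^2))`; the per-unit
#' sampling variance of the raw estimate is obtained by a
#' leave-one-sample-out jackknife. Units with zero mean in both groups are
#' excluded and reported in the `excluded` field.
#'
#' @param counts Integer matrix, units x samples.
#' @param groups Factor (2 levels) or vector assigning columns to groups.
#' @param size_factors Optional per-sample factors; computed via
#'   [size_factors()] when `NULL`.
#' @param pool Use the pooled within-group variance (default). With
#'   `pool = FALSE` the overall variance across all samples is used, which
#'   absorbs any group difference into the dispersion.
#' @param grid_length Number of candidate shrinkage targets.
#' @return A `dispersion_estimates` list with elements `table` (unit_id,
#'   raw, shrunk), `target`, `delta` and `excluded`.
#' @export
shrunk_dispersions <- function(counts, groups, size_factors = NULL,
                               pool = TRUE, grid_length = 200) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop2("`groups` must have exactly 2 levels")
  if (length(groups) != ncol(counts))
    stop2("`groups` length must match the number of columns")
  if (is.null(size_factors)) size_factors <- size_factors(counts)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("unit", seq_len(nrow(counts)))
  norm <- sweep(counts, 2, size_factors, "/")

  keep <- rowMeans(norm) > 0
  excluded <- ids[!keep]
  norm <- norm[keep, , drop = FALSE]
  n <- ncol(norm)
  if (!pool) groups <- factor(rep("all", n))
  glev <- levels(droplevels(groups))

  # Group sums and sums of squares give the pooled variance and its
  # leave-one-sample-out updates in closed form.
  S <- lapply(glev, function(lv) rowSums(norm[, groups == lv, drop = FALSE]))
  Q <- lapply(glev, function(lv) rowSums(norm[, groups == lv, drop = FALSE]^2))
  nk <- vapply(glev, function(lv) sum(groups == lv), numeric(1))
  if (sum(nk - 1) <= 0) stop2("need at least 2 samples in some group")

  mom_phi <- function(S, Q, nk) {
    css <- Map(function(s, q, m) q - s^2 / m, S, Q, as.list(nk))
    s2 <- Reduce(`+`, css) / (sum(nk) - length(nk))
    mu <- Reduce(`+`, S) / sum(nk)
    ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  }
  raw <- mom_phi(S, Q, nk)

  # Jackknife sampling variance of the raw estimator.
  acc1 <- numeric(nrow(norm)); acc2 <- numeric(nrow(norm))
  for (j in seq_len(n)) {
    k <- match(as.character(groups[j]), glev)
    if (nk[k] < 2) next
    Sj <- S; Qj <- Q; nj <- nk
    Sj[[k]] <- S[[k]] - norm[, j]
    Qj[[k]] <- Q[[k]] - norm[, j]^2
    nj[k] <- nk[k] - 1
    phi_j <- mom_phi(Sj, Qj, nj)
    acc1 <- acc1 + phi_j
    acc2 <- acc2 + phi_j^2
  }
  v_jack <- pmax(0, (n - 1) / n * (acc2 - acc1^2 / n))

  grid <- seq(0, max(raw, 1e-8), length.out = grid_length)
  ss <- vapply(grid, function(x) sum((raw - x)^2), numeric(1))
  xi <- grid[which.min(ss)]
  denom <- sum((raw - xi)^2)
  delta <- if (denom <= 0) 1 else min(1, sum(v_jack) / denom)
  shrunk <- delta * xi + (1 - delta) * raw

  structure(list(table = data.frame(unit_id = ids[keep], raw = raw,
                                    shrunk = shrunk,
                                    stringsAsFactors = FALSE),
                 target = xi, delta = delta, excluded = excluded),
            class = "dispersion_estimates")
}

#' Exact NB two-group test
#'
#' Two-sided exact-style test per unit: conditional on the total of the
#' size-factor-normalized group sums, the two-sided p-value sums the
#' probabilities of all splits no more likely than the observed one
#' (minimum-likelihood convention, ties included) under a shared-mean NB
#' model with the unit's shrunk dispersion and effective library sizes
#' equalized by the normalization. The log2 fold change is computed from
#' normalized group means with a pseudo-count of 1.
#'
#' @param counts Integer matrix, units x samples.
#' @param groups Factor with 2 levels; the fold change is level 2 over
#'   level 1.
#' @param dispersions A `dispersion_estimates` object (or a named numeric
#'   vector of per-unit dispersions).
#' @param size_factors Per-sample normalization factors.
#' @return A `de_table` data frame with columns `unit_id`, `base_mean`,
#'   `log2_fc`, `p`, `q`; units excluded at the dispersion stage are absent
#'   and listed in `attr(, "excluded")`.
#' @export
nb_test <- function(counts, groups, dispersions, size_factors) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop2("`groups` must have exactly 2 levels")
  if (any(table(groups) < 1)) stop2("each group needs at least 1 sample")
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("unit", seq_len(nrow(counts)))
  if (inherits(dispersions, "dispersion_estimates")) {
    phi <- setNames(dispersions$table$shrunk, dispersions$table$unit_id)
    excluded <- dispersions$excluded
  } else {
    phi <- dispersions
    if (is.null(names(phi))) names(phi) <- ids
    excluded <- character()
  }
  keep <- ids %in% names(phi)
  excluded <- union(excluded, ids[!keep])
  counts <- counts[keep, , drop = FALSE]
  ids <- ids[keep]
  phi <- phi[ids]

  norm <- sweep(counts, 2, size_factors, "/")
  g2 <- levels(groups)[2]
  in2 <- groups == g2
  n1 <- sum(!in2); n2 <- sum(in2)
  k1 <- round(rowSums(norm[, !in2, drop = FALSE]))
  k2 <- round(rowSums(norm[, in2, drop = FALSE]))
  m1 <- rowMeans(norm[, !in2, drop = FALSE])
  m2 <- rowMeans(norm[, in2, drop = FALSE])

  p <- vapply(seq_along(ids), function(i)
    nb_exact_p(k1[i], k2[i], n1, n2, phi[i]), numeric(1))

  res <- data.frame(unit_id = ids,
                    base_mean = rowMeans(norm),
                    log2_fc = log2((m2 + 1) / (m1 + 1)),
                    p = p,
                    q = adjust_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_table", "data.frame")
  attr(res, "excluded") <- excluded
  attr(res, "params") <- list(group1 = levels(groups)[1], group2 = g2,
                              pseudo_count = 1)
  res
}

# Conditional two-sided exact p for one unit. Group sums of n iid NB(mu,
# phi) are NB(n * mu, dispersion phi / n); conditioning on k1 + k2 = S
# removes the common mean scale.
nb_exact_p <- function(k1, k2, n1, n2, phi) {
  S <- k1 + k2
  if (S == 0) return(1)
  mu_hat <- S / (n1 + n2)
  a <- 0:S
  if (phi < 1e-12) {
    lp1 <- dpois(a, n1 * mu_hat, log = TRUE)
    lp2 <- dpois(a, n2 * mu_hat, log = TRUE)
  } else {
    lp1 <- dnbinom(a, mu = n1 * mu_hat, size = n1 / phi, log = TRUE)
    lp2 <- dnbinom(a, mu = n2 * mu_hat, size = n2 / phi, log = TRUE)
  }
  lp <- lp1 + rev(lp2)              # log P(split = (a, S - a))
  obs <- lp[k1 + 1]
  sel <- lp <= obs + 1e-7           # ties included
  exp(logsumexp(lp[sel]) - logsumexp(lp))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (the convention behind every FDR threshold in
#' this package), capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Threshold a DE table on FDR and fold change
#'
#' @param table A `de_table`.
#' @param alpha FDR threshold in `(0, 1)`.
#' @param fc_threshold Linear fold-change threshold (>= 1).
#' @return List with character vectors `up` and `down` of unit ids
#'   satisfying `q < alpha` and fold change strictly above the threshold in
#'   the respective direction.
#' @export
de_with_fc_filter <- function(table, alpha = 0.05, fc_threshold = 1.5) {
  if (alpha <= 0 || alpha >= 1) stop2("`alpha` must be in (0, 1)")
  if (fc_threshold < 1) stop2("`fc_threshold` must be >= 1")
  sig <- table$q < alpha
  list(up = table$unit_id[sig & 2^table$log2_fc > fc_threshold],
       down = table$unit_id[sig & 2^(-table$log2_fc) > fc_threshold])
}
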