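#' Regulon objects
#'
#' A regulon is a transcription factor together with its inferred target
#' set, a mode (`activating`, `repressing` or `unsigned`), per-target
#' run-support counts and a provenance label.
#'
#' @param tf Regulator gene id.
#' @param mode One of `"activating"`, `"repressing"`, `"unsigned"`.
#' @param targets Non-empty character vector of target gene ids (no
#'   duplicates, never the TF itself).
#' @param support_runs Integer vector (recycled) of per-target run support.
#' @param provenance One of `"consensus"`, `"custom_overexpression"`,
#'   `"custom_dual_contrast"`, `"single_run"`.
#' @return A `regulon` list.
#' @export
regulon <- function(tf, mode = c("activating", "repressing", "unsigned"),
                    targets, support_runs = 1L,
                    provenance = c("consensus", "custom_overexpression",
                                   "custom_dual_contrast", "single_run")) {
  mode <- match.arg(mode)
  provenance <- match.arg(provenance)
  if (length(targets) == 0) stop2("regulon target set must be non-empty")
  if (anyDuplicated(targets)) stop2("duplicate targets in regulon")
  if (tf %in% targets) stop2("a regulon may not contain its own TF")
  ord <- order(targets)
  structure(list(tf = tf, mode = mode, targets = targets[ord],
                 support_runs = setNames(rep_len(as.integer(support_runs),
                                                 length(targets))[ord],
                                         targets[ord]),
                 provenance = provenance),
            class = "regulon")
}

#' @rdname regulon
#' @param x A regulon.
#' @export
regulon_label <- function(x) {
  suffix <- switch(x$mode, activating = "(+)", repressing = "(-)", "")
  paste0(x$tf, suffix)
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d targets [%s]\n", regulon_label(x),
              length(x$targets), x$provenance))
  invisible(x)
}

#' Boolean motif-support tables
#'
#' A (tf, gene) lookup stating whether the gene carries motif support for
#' the TF near its TSS; every pair is queryable and defaults to `FALSE`.
#'
#' @param df Data frame with columns `tf`, `gene` and logical `supported`.
#' @return A `motif_support` object.
#' @export
motif_support <- function(df) {
  if (is.null(df$supported)) df$supported <- TRUE
  df <- df[df$supported, c("tf", "gene"), drop = FALSE]
  structure(list(keys = unique(paste(df$tf, df$gene, sep = "\r"))),
            class = "motif_support")
}

#' @rdname motif_support
#' @param support A `motif_support` object.
#' @param tf,gene Vectors (recycled) to query.
#' @export
is_supported <- function(support, tf, gene) {
  paste(tf, gene, sep = "\r") %in% support$keys
}

#' Derive motif support from TF hit regions near gene TSSs
#'
#' A gene is supported for a TF when any of the TF's motif-hit regions lies
#' within `window` bp of the gene's TSS (the conventional +/- 10 kb
#' TSS-centred gene space).
#'
#' @param hits Named list (by TF) of [region_set()]s of motif hits.
#' @param annotation A [gene_annotation()].
#' @param window Support window in bp, default 10000.
#' @return A `motif_support` object.
#' @export
motif_support_from_regions <- function(hits, annotation, window = 10000) {
  rows <- lapply(names(hits), function(tf) {
    d <- min_peak_distance(annotation, hits[[tf]])
    data.frame(tf = tf, gene = names(d)[d <= window], supported = TRUE,
               stringsAsFactors = FALSE)
  })
  motif_support(do.call(rbind, rows))
}

#' Score TF-to-target adjacencies with a seeded tree ensemble
#'
#' For each candidate target gene, the importance of every TF is taken from
#' a seeded random-forest regression of the target's log-normalized
#' expression on the TF expressions, together with the Spearman correlation
#' sign used downstream to orient regulons. Constant targets receive zero
#' importance for every TF.
#'
#' @param expr A `cell_matrix` (or counts matrix).
#' @param tf_list TFs to use as predictors (must be rows of the matrix).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param targets Candidate targets; default all non-TF genes.
#' @param num_trees Trees per ensemble.
#' @return An `adjacency` data frame (tf, target, importance, rho,
#'   run_seed).
#' @export
score_adjacencies <- function(expr, tf_list, seed = 1, targets = NULL,
                              num_trees = 50) {
  counts <- if (inherits(expr, "cell_matrix")) expr$counts else as.matrix(expr)
  if (!all(tf_list %in% rownames(counts)))
    stop2("every TF must be a row of the expression matrix")
  if (ncol(counts) < 50) stop2("need at least 50 cells")
  if (is.null(targets)) targets <- setdiff(rownames(counts), tf_list)
  sf <- colSums(counts); sf <- sf / mean(sf)
  logx <- log2(1 + sweep(counts[c(tf_list, targets), , drop = FALSE], 2,
                         sf, "/"))
  X <- t(logx[tf_list, , drop = FALSE])
  colnames(X) <- tf_list

  # Spearman sign, all TFs x targets at once
  rk <- apply(logx, 1, rank)           # cells x genes
  rho <- suppressWarnings(cor(rk[, tf_list, drop = FALSE],
                              rk[, targets, drop = FALSE]))
  rho[is.na(rho)] <- 0

  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    y <- logx[targets[i], ]
    if (var(y) == 0 || var(counts[targets[i], ]) == 0) {
      imp <- setNames(rep(0, length(tf_list)), tf_list)
    } else {
      fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                            importance = "impurity",
                            seed = seed + i, num.threads = 1,
                            respect.unordered.factors = "order")
      imp <- fit$variable.importance[tf_list]
      imp[is.na(imp) | imp < 0] <- 0
    }
    res[[i]] <- data.frame(tf = tf_list, target = targets[i],
                           importance = unname(imp),
                           rho = rho[tf_list, targets[i]],
                           run_seed = seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("adjacency", "data.frame")
  out
}

#' Prune adjacencies by motif support into single-run regulons
#'
#' Per TF, keeps the `top_k_per_tf` targets by importance and retains only
#' those with motif support; survivors are split into an activating and a
#' repressing regulon by the sign of the TF-target co-expression
#' correlation. TFs with no surviving target yield no regulon.
#'
#' @param adjacencies An `adjacency` data frame from [score_adjacencies()].
#' @param support A `motif_support` object.
#' @param top_k_per_tf Targets retained per TF before the support filter.
#' @return A `regulon_set` (named list of regulons keyed by label).
#' @export
prune_by_motif <- function(adjacencies, support, top_k_per_tf = 100) {
  if (top_k_per_tf < 1) stop2("`top_k_per_tf` must be >= 1")
  out <- list()
  for (tf in unique(adjacencies$tf)) {
    a <- adjacencies[adjacencies$tf == tf & adjacencies$importance > 0, ,
                     drop = FALSE]
    a <- a[order(-a$importance, a$target), , drop = FALSE]
    a <- head(a, top_k_per_tf)
    a <- a[is_supported(support, tf, a$target), , drop = FALSE]
    if (nrow(a) == 0) next
    for (mode in c("activating", "repressing")) {
      t <- if (mode == "activating") a$target[a$rho >= 0] else
        a$target[a$rho < 0]
      if (length(t) == 0) next
      r <- regulon(tf, mode, t, 1L, provenance = "single_run")
      out[[regulon_label(r)]] <- r
    }
  }
  as_regulon_set(out)
}

as_regulon_set <- function(x) structure(x, class = "regulon_set")

#' Multi-run consensus regulons
#'
#' The stability rule for stochastic regulon inference: a (TF, mode)
#' regulon is emitted only when its regulator was identified in every one
#' of the `n_runs` runs; its target set is the union of per-run targets
#' restricted to targets appearing in at least `min_target_runs` runs, each
#' annotated with its run support.
#'
#' @param runs List of `regulon_set`s, one per run (length `n_runs`).
#' @param n_runs Expected number of runs; default 5.
#' @param min_target_runs Minimum per-target run support; default 2.
#' @return A `regulon_set` with provenance `consensus`.
#' @export
consensus_regulons <- function(runs, n_runs = 5, min_target_runs = 2) {
  if (length(runs) == 0) stop2("empty run list")
  if (length(runs) != n_runs)
    stop2("expected ", n_runs, " runs, got ", length(runs))
  keys <- lapply(runs, names)
  common <- Reduce(intersect, keys)
  out <- list()
  for (key in sort(common)) {
    regs <- lapply(runs, `[[`, key)
    support <- table(unlist(lapply(regs, `[[`, "targets")))
    keep <- names(support)[support >= min_target_runs]
    if (length(keep) == 0) next
    keep <- sort(keep)
    r <- regulon(regs[[1]]$tf, regs[[1]]$mode, keep,
                 as.integer(support[keep]), provenance = "consensus")
    out[[key]] <- r
  }
  as_regulon_set(out)
}

#' Merge consensus and custom regulon sources
#'
#' Union keyed by (tf, mode): custom regulons never overwrite consensus
#' regulons with the same key; they are carried alongside under their own
#' provenance. Duplicate (tf, mode, provenance) combinations are an error.
#'
#' @param consensus,custom `regulon_set`s.
#' @return A `regulon_set`.
#' @export
merge_regulon_sources <- function(consensus, custom) {
  all_regs <- c(unname(as.list(consensus)), unname(as.list(custom)))
  sig <- vapply(all_regs, function(r)
    paste(r$tf, r$mode, r$provenance, sep = "|"), character(1))
  if (anyDuplicated(sig))
    stop2("duplicate (tf, mode, provenance): ",
          paste(unique(sig[duplicated(sig)]), collapse = ", "))
  ord <- order(vapply(all_regs, regulon_label, character(1)),
               vapply(all_regs, `[[`, character(1), "provenance"))
  all_regs <- all_regs[ord]
  names(all_regs) <- vapply(all_regs, regulon_label, character(1))
  as_regulon_set(all_regs)
}

#' Run seeded inference-plus-pruning multiple times and take the consensus
#'
#' Convenience wrapper: runs [score_adjacencies()] + [prune_by_motif()]
#' with seeds `base_seed + 0:(n_runs-1)` and applies
#' [consensus_regulons()].
#'
#' @inheritParams score_adjacencies
#' @inheritParams prune_by_motif
#' @inheritParams consensus_regulons
#' @param base_seed Base seed; run `i` uses `base_seed + i - 1`.
#' @return A `regulon_set`.
#' @export
run_consensus_grn <- function(expr, tf_list, support, base_seed = 1,
                              n_runs = 5, min_target_runs = 2,
                              top_k_per_tf = 100, targets = NULL,
                              num_trees = 50) {
  runs <- lapply(seq_len(n_runs) - 1L, function(k) {
    adj <- score_adjacencies(expr, tf_list, seed = base_seed + k,
                             targets = targets, num_trees = num_trees)
    prune_by_motif(adj, support, top_k_per_tf = top_k_per_tf)
  })
  consensus_regulons(runs, n_runs = n_runs,
                     min_target_runs = min_target_runs)
}

#' Read and write regulons as GMT and JSON
#'
#' GMT: one line per regulon, set name `TF(+)` / `TF(-)`, description
#' field carrying the provenance, then the sorted targets. JSON carries the
#' per-target support counts as well. Output bytes are deterministic for
#' identical inputs.
#'
#' @param regulons A `regulon_set`.
#' @param path Output path.
#' @export
write_gmt <- function(regulons, path) {
  lines <- vapply(regulons, function(r)
    paste(c(regulon_label(r), r$provenance, r$targets), collapse = "\t"),
    character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unname(lines), con, sep = "\n")
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  out <- list()
  for (ln in readLines(path)) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) next
    tf <- sub("\\([+-]\\)$", "", f[1])
    mode <- if (grepl("\\(\\+\\)$", f[1])) "activating" else
      if (grepl("\\(-\\)$", f[1])) "repressing" else "unsigned"
    prov <- if (f[2] %in% c("consensus", "custom_overexpression",
                            "custom_dual_contrast", "single_run")) f[2] else
      "single_run"
    r <- regulon(tf, mode, f[-(1:2)], provenance = prov)
    out[[regulon_label(r)]] <- r
  }
  as_regulon_set(out)
}

#' @rdname write_gmt
#' @export
write_regulons_json <- function(regulons, path) {
  payload <- lapply(unname(as.list(regulons)), function(r)
    list(tf = r$tf, mode = r$mode, provenance = r$provenance,
         targets = as.list(setNames(as.integer(r$support_runs),
                                    r$targets))))
  names(payload) <- vapply(regulons, regulon_label, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
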