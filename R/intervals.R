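#' Build fixed-width regions centred on peak summits
#'
#' Re-derives fixed-width peak regions from summit positions, the standard
#' treatment of MACS output before merging: each region spans
#' `[summit - width/2, summit + width/2)`, clipped at position 0.
#'
#' @param summits A [region_set()] whose records all carry `summit_offset`.
#' @param width Region width in bp (even); default 200.
#' @return A [region_set()] of summit-centred windows.
#' @export
summit_windows <- function(summits, width = 200) {
  if (width <= 0 || width %% 2 != 0)
    stop2("`width` must be a positive even number")
  if (nrow(summits) == 0) return(summits)
  if (any(is.na(summits$summit_offset)))
    stop2("all records must carry a summit_offset")
  summit <- summits$start + summits$summit_offset
  start <- pmax(0, summit - width / 2)
  end <- summit + width / 2
  region_set(summits$chrom, start, end, summits$name, summits$score,
             summit - start)
}

#' Merge overlapping regions
#'
#' Combines overlapping regions into maximal covering intervals. Book-ended
#' regions (sharing only a boundary) are also joined; the union of covered
#' bases is preserved exactly.
#'
#' @param regions A [region_set()].
#' @return A sorted [region_set()] of pairwise non-overlapping regions.
#' @export
merge_overlapping <- function(regions) {
  granges_to_regions(GenomicRanges::reduce(regions_to_granges(regions)))
}

#' Regions supported by a minimum number of replicates
#'
#' Computes per-base replicate support (each replicate set counted once per
#' base, regardless of internal overlap) and returns the maximal intervals
#' covered by at least `min_support` replicate sets — the interval analogue
#' of combining replicate peak sets and keeping the replicated portion.
#'
#' @param replicates A non-empty list of [region_set()]s.
#' @param min_support Minimum number of supporting replicates.
#' @return A [region_set()].
#' @export
replicated_regions <- function(replicates, min_support) {
  if (length(replicates) == 0) stop2("`replicates` must be non-empty")
  if (min_support < 1 || min_support > length(replicates))
    stop2("`min_support` must be in [1, number of replicates]")
  chroms <- sort(unique(unlist(lapply(replicates, function(r) r$chrom))))
  pieces <- list()
  for (ch in chroms) {
    irl <- lapply(replicates, function(r) {
      rr <- r[r$chrom == ch, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(start = rr$start + 1, end = rr$end))
    })
    width <- max(vapply(irl, function(ir)
      if (length(ir)) max(IRanges::end(ir)) else 0L, numeric(1)))
    if (width == 0) next
    cov <- Reduce(`+`, lapply(irl, IRanges::coverage, width = width))
    hit <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    if (length(hit) == 0) next
    pieces[[ch]] <- data.frame(chrom = ch,
                               start = IRanges::start(hit) - 1,
                               end = IRanges::end(hit))
  }
  if (length(pieces) == 0)
    return(region_set(character(), numeric(), numeric()))
  df <- do.call(rbind, pieces)
  region_set(df$chrom, df$start, df$end)
}

#' Regions unique to one class
#'
#' For labelled region sets (one per population class), returns for each
#' class the regions that share no base with any region of any other class.
#'
#' @param class_sets Named list (>= 2 entries) of [region_set()]s.
#' @return Named list of [region_set()]s, pairwise disjoint across classes.
#' @export
class_unique_regions <- function(class_sets) {
  if (length(class_sets) < 2) stop2("need at least 2 classes")
  if (is.null(names(class_sets)) || any(names(class_sets) == ""))
    stop2("`class_sets` must be a named list")
  grl <- lapply(class_sets, regions_to_granges)
  out <- vector("list", length(class_sets))
  names(out) <- names(class_sets)
  for (i in seq_along(class_sets)) {
    others <- do.call(c, unname(grl[-i]))
    keep <- !IRanges::overlapsAny(grl[[i]], others, minoverlap = 1L)
    out[[i]] <- as_region_set(class_sets[[i]][keep, , drop = FALSE])
  }
  out
}

#' Distance from a region to a transcription start site
#'
#' Distance in bp between a half-open region and a TSS: 0 when the TSS lies
#' inside `[start, end)`, otherwise the distance to the nearer of the first
#' (`start`) and last (`end - 1`) contained base. Regions on a different
#' chromosome are infinitely far (they can never pass a window filter).
#' Strand affects only how a TSS is defined, never the distance.
#'
#' @param region A single-row [region_set()] (or list with chrom/start/end).
#' @param gene A single-row gene annotation entry with `chrom` and `tss`.
#' @return Distance in bp (possibly `Inf`).
#' @export
distance_to_tss <- function(region, gene) {
  if (region$chrom != gene$chrom) return(Inf)
  tss <- gene$tss
  if (tss >= region$start && tss < region$end) return(0)
  min(abs(tss - region$start), abs(tss - (region$end - 1)))
}

#' Minimum peak distance per gene
#'
#' For each gene, the minimum [distance_to_tss()] over all regions
#' (`Inf` when no region shares the gene's chromosome).
#'
#' @param annotation A [gene_annotation()].
#' @param regions A [region_set()].
#' @return Named numeric vector of distances, one per gene.
#' @export
min_peak_distance <- function(annotation, regions) {
  out <- rep(Inf, nrow(annotation))
  names(out) <- annotation$gene_id
  if (nrow(regions) == 0) return(out)
  merged <- merge_overlapping(regions)   # preserves nearest covered base
  for (ch in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == ch)
    rr <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(rr) == 0) next
    tss <- annotation$tss[gi]
    i <- findInterval(tss, rr$start)
    d <- rep(Inf, length(tss))
    has_left <- i >= 1
    il <- pmax(i, 1)
    inside <- has_left & tss < rr$end[il]
    d[has_left] <- tss[has_left] - (rr$end[il[has_left]] - 1)
    d[inside] <- 0
    has_right <- i < nrow(rr)
    ir <- pmin(i + 1, nrow(rr))
    d_right <- rr$start[ir] - tss
    d[has_right] <- pmin(d[has_right], d_right[has_right])
    out[gi] <- pmin(out[gi], d)
  }
  out
}

#' Coarse annotation of regions relative to gene TSSs
#'
#' Assigns each region `promoter` when its distance to the nearest TSS is
#' at most `promoter_window`, `proximal` when at most ten times that
#' (both thresholds inclusive), otherwise `distal`.
#'
#' @param regions A [region_set()].
#' @param annotation A [gene_annotation()] data frame.
#' @param promoter_window Promoter distance in bp (> 0).
#' @return Character vector of categories, one per region.
#' @export
annotate_regions <- function(regions, annotation, promoter_window = 1000) {
  if (promoter_window <= 0) stop2("`promoter_window` must be > 0")
  if (nrow(annotation) == 0) stop2("`annotation` is empty")
  d <- region_tss_distance(regions, annotation)
  ifelse(d <= promoter_window, "promoter",
         ifelse(d <= 10 * promoter_window, "proximal", "distal"))
}

# Per-region minimum distance_to_tss over all annotated genes.
region_tss_distance <- function(regions, annotation) {
  d <- rep(Inf, nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    tss <- sort(annotation$tss[annotation$chrom == ch])
    if (length(tss) == 0) next
    s <- regions$start[ri]; e <- regions$end[ri]
    hi <- findInterval(e - 1, tss)             # last tss <= e-1
    lo <- findInterval(s - 1, tss)             # last tss <  s
    dd <- rep(Inf, length(ri))
    dd[hi > lo] <- 0                           # some tss inside [s, e)
    has_left <- lo >= 1
    dd[has_left] <- pmin(dd[has_left],
                         s[has_left] - tss[pmax(lo[has_left], 1)])
    has_right <- hi < length(tss)
    dd[has_right] <- pmin(dd[has_right],
                          tss[pmin(hi[has_right] + 1, length(tss))] -
                            (e[has_right] - 1))
    d[ri] <- dd
  }
  d
}

#' Gene annotation tables
#'
#' A minimal gene-level annotation: one canonical TSS and strand per gene,
#' in 0-based coordinates. When built from transcript-level input the most
#' upstream transcript start per strand is taken as the gene TSS.
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome per gene.
#' @param strand `"+"` or `"-"`.
#' @param tss 0-based TSS position.
#' @param symbol Optional symbols.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, symbol = NA) {
  if (anyDuplicated(gene_id)) stop2("gene_id must be unique")
  if (!all(strand %in% c("+", "-"))) stop2("strand must be '+' or '-'")
  if (any(tss < 0)) stop2("tss must be >= 0")
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @rdname gene_annotation
#' @param path TSV with columns gene_id, chrom, strand, tss (and optional
#'   symbol).
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_annotation(df$gene_id, df$chrom, df$strand, df$tss,
                  if (is.null(df$symbol)) NA else df$symbol)
}

#' @rdname gene_annotation
#' @param annotation A `gene_annotation` to write.
#' @export
write_gene_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse transcript records of a GTF to gene-level TSSs
#'
#' Reads `transcript` records from a GTF (1-based closed coordinates,
#' converted to 0-based internally) and collapses to one TSS per gene: the
#' most upstream transcript start on the gene's strand.
#'
#' @param path GTF file path.
#' @return A [gene_annotation()].
#' @export
read_gtf_tss <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "#", stringsAsFactors = FALSE)
  df <- df[df$V3 == "transcript", , drop = FALSE]
  if (nrow(df) == 0) stop2("no transcript records in GTF")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", df$V9)
  start0 <- df$V4 - 1                      # GTF is 1-based closed
  tss <- ifelse(df$V7 == "+", start0, df$V5 - 1)
  pick <- tapply(seq_along(gid), gid, function(ix) {
    if (df$V7[ix[1]] == "+") ix[which.min(tss[ix])] else ix[which.max(tss[ix])]
  })
  ix <- unlist(pick)
  gene_annotation(gid[ix], df$V1[ix], df$V7[ix], tss[ix])
}
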