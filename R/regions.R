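#' Genomic region sets
#'
#' A `region_set` is a data frame of genomic intervals in 0-based half-open
#' (BED) coordinates with columns `chrom`, `start`, `end` and optional
#' `name`, `score` and `summit_offset` (offset of a peak summit from
#' `start`, in `[0, end - start)`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`, half-open.
#' @param name Optional region names.
#' @param score Optional numeric scores.
#' @param summit_offset Optional integer summit offsets from `start`.
#' @return A `region_set` data frame sorted by `(chrom, start, end)`.
#' @export
region_set <- function(chrom, start, end, name = NA_character_,
                       score = NA_real_, summit_offset = NA_integer_) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0) n <- 0
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   summit_offset = rep_len(as.numeric(summit_offset), n),
                   stringsAsFactors = FALSE)
  validate_region_set(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

validate_region_set <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop2("region starts must be >= 0")
  if (any(df$end <= df$start)) stop2("regions must satisfy start < end")
  so <- df$summit_offset
  ok <- is.na(so) | (so >= 0 & so < df$end - df$start)
  if (!all(ok)) stop2("summit_offset must lie in [0, end - start)")
  invisible(df)
}

as_region_set <- function(df) {
  for (col in c("name", "score", "summit_offset"))
    if (is.null(df[[col]])) df[[col]] <- NA
  region_set(df$chrom, df$start, df$end, df$name, df$score, df$summit_offset)
}

# 0-based half-open -> GRanges (1-based closed).
regions_to_granges <- function(rs) {
  if (nrow(rs) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1, end = rs$end))
}

granges_to_regions <- function(gr) {
  if (length(gr) == 0)
    return(region_set(character(), numeric(), numeric()))
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1,
             GenomicRanges::end(gr))
}

#' Read and write BED and narrowPeak files
#'
#' BED coordinates are kept 0-based half-open. `read_narrowpeak()` maps the
#' tenth column (summit offset from `start`; `-1` for unknown) onto
#' `summit_offset`.
#'
#' @param path File path.
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  as_region_set(df)
}

#' @rdname read_bed
#' @param regions A [region_set()] to write.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, format_coord(regions$start),
                   format_coord(regions$end),
                   ifelse(is.na(regions$name), ".", regions$name),
                   ifelse(is.na(regions$score), 0, regions$score),
                   ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 10) stop2("narrowPeak requires 10 columns")
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak")
  df$summit_offset <- ifelse(df$peak < 0, NA_real_, df$peak)
  as_region_set(df)
}

#' @rdname read_bed
#' @export
write_narrowpeak <- function(regions, path) {
  df <- data.frame(regions$chrom, format_coord(regions$start),
                   format_coord(regions$end),
                   ifelse(is.na(regions$name), ".", regions$name),
                   ifelse(is.na(regions$score), 0, regions$score),
                   ".", 0, -1, -1,
                   ifelse(is.na(regions$summit_offset), -1,
                          format_coord(regions$summit_offset)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
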