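#' Read and write single-cell counts as an MTX triplet
#'
#' The 10x-style layout: `matrix.mtx` (MatrixMarket sparse counts),
#' `features.tsv` (gene ids), `barcodes.tsv` (cell ids) and, when cell
#' metadata is present, `cell_metadata.tsv`.
#'
#' @param cells A `cell_matrix`.
#' @param dir Directory to write into (created if needed).
#' @export
write_counts_mtx <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(cells$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(cells$cell_meta))
    write.table(cells$cell_meta, file.path(dir, "cell_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @return `read_counts_mtx()`: a `cell_matrix`.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_metadata.tsv")
  meta <- if (file.exists(meta_path))
    read.table(meta_path, sep = "\t", header = TRUE,
               stringsAsFactors = FALSE) else NULL
  structure(list(counts = m, cell_meta = meta), class = "cell_matrix")
}

#' Read and write gene x sample count tables as TSV
#'
#' @param counts Integer matrix with row and column names.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(unit_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a DE table with a YAML parameter sidecar
#'
#' @param table A `de_table`.
#' @param path TSV output path; the sidecar is written to `<path>.yaml`.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params <- attr(table, "params")
  if (!is.null(params))
    yaml::write_yaml(params, paste0(path, ".yaml"))
  invisible(path)
}

#' Read and write simulation configs as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$cell_groups <- as.list(cfg$cell_groups)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cell_groups <- as.data.frame(cfg$cell_groups,
                                   stringsAsFactors = FALSE)
  do.call(sim_config, cfg)
}

#' Write a complete synthetic fixture to disk
#'
#' Counts as an MTX triplet, peaks as BED and narrowPeak, the gene
#' annotation and truth tables as TSV, and the config as YAML.
#'
#' @param truth A `planted_network`.
#' @param cells A `cell_matrix`.
#' @param peaks A `peak_simulation`.
#' @param bulk A `bulk_experiment` (optional).
#' @param dir Output directory.
#' @export
write_simulation <- function(truth, cells, peaks, bulk = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(cells, dir)
  write_bed(peaks$peaks, file.path(dir, "peaks.bed"))
  write_narrowpeak(peaks$peaks, file.path(dir, "peaks.narrowPeak"))
  write_gene_annotation(truth$annotation, file.path(dir, "annotation.tsv"))
  write.table(truth$edges, file.path(dir, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bulk)) {
    write_counts_tsv(bulk$counts, file.path(dir, "bulk_counts.tsv"))
    write.table(bulk$sample_meta, file.path(dir, "bulk_samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_sim_config(truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
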