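# Shared fixtures. The small config keeps unit tests fast; the full study
# (the package's default conditions) is run once and cached for the
# acceptance-level checks.

small_config <- function(...) {
  sim_config(n_genes = 400, n_activated = 40, n_repressed = 40,
             cell_groups = data.frame(
               genotype = c("WT", "KO"),
               cell_type = c("mesoderm", "mesoderm"),
               n = c(300, 300), stringsAsFactors = FALSE),
             decoy_peak_count = 50, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

default_study <- function() {
  cached("default_study", function() run_target_pipeline(sim_config(),
                                                         seed = 1))
}

# Random small region set on one or two chromosomes with small coordinates,
# for brute-force comparisons.
random_regions <- function(n, max_pos = 1000, chroms = c("chrA", "chrB")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(50, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), start, start + width)
}

# Per-base occupancy oracle: which bases (chrom, pos) are covered by a set.
covered_bases <- function(rs, max_pos = 2000) {
  out <- list()
  for (ch in unique(rs$chrom)) {
    v <- logical(max_pos)
    rr <- rs[rs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rr)))
      v[(rr$start[i] + 1):rr$end[i]] <- TRUE
    out[[ch]] <- v
  }
  out
}
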