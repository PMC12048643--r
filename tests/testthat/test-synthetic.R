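test_that("truth generation is deterministic and respects the config", {
  cfg <- small_config()
  t1 <- generate_truth(cfg, seed = 1)
  t2 <- generate_truth(cfg, seed = 1)
  expect_identical(t1, t2)
  expect_false(identical(t1$edges, generate_truth(cfg, seed = 2)$edges))

  cfg300 <- sim_config(n_activated = 300, n_repressed = 300)
  tr <- generate_truth(cfg300, seed = 3)
  expect_equal(nrow(tr$edges), 600)
  expect_equal(sum(tr$edges$sign == 1), 300)
  expect_true(all(tr$edges$beta > 0))
  expect_false(any(duplicated(tr$edges[c("tf", "target")])))
  expect_false(any(tr$edges$tf == tr$edges$target))
  expect_true(all(tr$genes$baseline_mu > 0))
  expect_true(all(tr$genes$phi >= 0))
})

test_that("requesting more targets than genes is an error", {
  expect_error(generate_truth(sim_config(n_genes = 100, n_activated = 60,
                                         n_repressed = 60), 1),
               "more targets")
  expect_error(generate_truth(sim_config(n_activated = 5), 1),
               "at least 10")
})

test_that("knockout cells have zero regulator counts and baseline targets", {
  cfg <- small_config()
  tr <- generate_truth(cfg, 1)
  cells <- simulate_cells(tr, cfg, 2)
  ko <- cells$cell_meta$genotype == "KO"
  expect_true(all(cells$counts[tr$tf_ids[1], ko] == 0))
  expect_identical(cells, simulate_cells(tr, cfg, 2))
  expect_true(all(cells$cell_meta$activity[ko] == 0))

  # with activity 0 everywhere the beta exponent vanishes: per-gene KO means
  # track sf-weighted baselines
  sf_mean <- mean(cells$cell_meta$size_factor[ko])
  mu <- tr$genes$baseline_mu
  obs <- rowMeans(cells$counts[, ko, drop = FALSE])
  targets <- tr$genes$role %in% c("activated", "repressed")
  big <- targets & mu > 3
  expect_lt(median(abs(obs[big] / (mu[big] * sf_mean) - 1)), 0.15)
})

test_that("simulated counts obey the NB mean-variance law", {
  cfg <- sim_config(n_genes = 40, n_activated = 10, n_repressed = 10,
                    n_housekeeping = 5, phi = 0.2, libsize_sigma = 0,
                    cell_groups = data.frame(genotype = "KO",
                                             cell_type = "mesoderm",
                                             n = 6000,
                                             stringsAsFactors = FALSE))
  tr <- generate_truth(cfg, 5)
  cells <- simulate_cells(tr, cfg, 6)
  mu_hat <- rowMeans(cells$counts)
  v_hat <- apply(cells$counts, 1, var)
  keep <- tr$genes$role != "tf" & mu_hat > 2    # stable moment estimates
  ratio <- v_hat[keep] / (mu_hat[keep] + 0.2 * mu_hat[keep]^2)
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("proximal peaks pass and decoys fail the window filter", {
  cfg <- small_config(proximal_peak_fraction = 1.0)
  tr <- generate_truth(cfg, 1)
  pk <- simulate_peaks(tr, cfg, 2)
  expect_true(all(pk$peaks$end - pk$peaks$start == 200))
  d <- min_peak_distance(tr$annotation, pk$peaks)

  # every true target passes with fraction 1.0
  expect_true(all(d[tr$edges$target] <= pk$window))
  # decoys alone never reach a true-target TSS
  decoys <- pk$peaks[grepl("^decoy", pk$peaks$name), , drop = FALSE]
  dd <- min_peak_distance(
    tr$annotation[tr$annotation$gene_id %in% tr$edges$target, ], decoys)
  expect_true(all(dd > pk$window))
})

test_that("window-passing genes are exactly proximal targets plus incidentals", {
  cfg <- small_config()
  tr <- generate_truth(cfg, 3)
  pk <- simulate_peaks(tr, cfg, 4)
  d <- min_peak_distance(tr$annotation, pk$peaks)
  passing <- sort(names(d)[d <= pk$window])
  expect_identical(passing, pk$passing_genes)
  expect_identical(pk$passing_genes,
                   sort(union(pk$proximal_targets, pk$incidental_genes)))
  expect_error(simulate_peaks(tr, sim_config(window = 1e9), 1),
               "larger than a chromosome")
})

test_that("induction bulk has 3 replicates per arm and planted structure", {
  cfg <- small_config()
  tr <- generate_truth(cfg, 1)
  bulk <- simulate_induction_bulk(tr, cfg, 2)
  expect_equal(as.vector(table(bulk$sample_meta$arm)), rep(3L, 4))

  # confounders shift in both induced arms
  conf <- bulk$confounder_genes
  ind <- bulk$sample_meta$arm == "induced"
  ctl <- bulk$sample_meta$arm == "control"
  cind <- bulk$sample_meta$arm == "confounder_induced"
  cctl <- bulk$sample_meta$arm == "confounder_control"
  lfc1 <- log2(rowMeans(bulk$counts[conf, ind]) /
                 rowMeans(bulk$counts[conf, ctl]))
  lfc2 <- log2(rowMeans(bulk$counts[conf, cind]) /
                 rowMeans(bulk$counts[conf, cctl]))
  expect_gt(median(lfc1), 0.7)
  expect_gt(median(lfc2), 0.7)

  # with no early targets, targets differ only by noise at induction
  cfg0 <- small_config(early_target_fraction = 0)
  tr0 <- generate_truth(cfg0, 1)
  b0 <- simulate_induction_bulk(tr0, cfg0, 2)
  expect_length(b0$early_targets, 0)
  tg <- tr0$edges$target
  lfc0 <- log2(rowMeans(b0$counts[tg, b0$sample_meta$arm == "induced"]) /
                 rowMeans(b0$counts[tg, b0$sample_meta$arm == "control"]))
  expect_lt(max(abs(lfc0)), 0.5)
})

test_that("MAD cell filter applies the floor and degenerate-spread rules", {
  counts <- matrix(100L, nrow = 10, ncol = 20,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  cm <- structure(list(counts = counts,
                       cell_meta = data.frame(cell_id = colnames(counts))),
                  class = "cell_matrix")
  expect_equal(ncol(mad_filter_cells(cm, floor = 0)$counts), 20)

  counts2 <- counts
  counts2[, 1] <- 0L
  counts2[1, 1] <- 1L
  cm2 <- structure(list(counts = counts2,
                        cell_meta = data.frame(cell_id = colnames(counts2))),
                   class = "cell_matrix")
  filt <- mad_filter_cells(cm2, floor = 500)
  expect_identical(attr(filt, "removed"), "c1")
  expect_equal(nrow(filt$cell_meta), 19)

  # column permutation changes nothing but order
  perm <- sample(ncol(counts2))
  cmp <- structure(list(counts = counts2[, perm],
                        cell_meta = data.frame(
                          cell_id = colnames(counts2)[perm])),
                   class = "cell_matrix")
  expect_setequal(attr(mad_filter_cells(cmp, floor = 500), "removed"), "c1")
  expect_error(mad_filter_cells(structure(list(counts = counts[, 0]),
                                          class = "cell_matrix")),
               "empty")
})

test_that("MAD filter is idempotent on the default small fixture", {
  cfg <- small_config()
  tr <- generate_truth(cfg, 1)
  cells <- simulate_cells(tr, cfg, 2)
  once <- mad_filter_cells(cells)
  twice <- mad_filter_cells(once)
  expect_identical(once$counts, twice$counts)
})
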