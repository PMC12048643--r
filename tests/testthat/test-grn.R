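grn_fixture <- function() {
  cached("grn_fixture", function() {
    cfg <- sim_config(n_genes = 250, n_activated = 30, n_repressed = 30,
                      tf_names = paste0("TF", 1:10), beta_range = c(2, 2),
                      cell_groups = data.frame(genotype = "WT",
                                               cell_type = "mesoderm",
                                               n = 2000,
                                               stringsAsFactors = FALSE))
    truth <- generate_truth(cfg, 11)
    list(cfg = cfg, truth = truth,
         cells = simulate_cells(truth, cfg, 12))
  })
}

test_that("a strong planted activator dominates tree-ensemble importances", {
  fx <- grn_fixture()
  act <- fx$truth$edges$target[fx$truth$edges$sign == 1]
  adj <- score_adjacencies(fx$cells, fx$truth$tf_ids, seed = 1,
                           targets = act, num_trees = 40)
  top1 <- vapply(split(adj, adj$target),
                 function(a) a$tf[which.max(a$importance)], character(1))
  expect_gte(mean(top1 == "TF1"), 0.9)
  # activated targets co-vary positively with the regulator
  rho_tf1 <- adj$rho[adj$tf == "TF1"]
  expect_gte(mean(rho_tf1 > 0), 0.95)
})

test_that("adjacency scoring is seed-deterministic and zeroes constants", {
  fx <- grn_fixture()
  some <- fx$truth$edges$target[1:5]
  a1 <- score_adjacencies(fx$cells, fx$truth$tf_ids, seed = 3,
                          targets = some, num_trees = 20)
  a2 <- score_adjacencies(fx$cells, fx$truth$tf_ids, seed = 3,
                          targets = some, num_trees = 20)
  expect_identical(a1, a2)

  cells0 <- fx$cells
  cells0$counts["G0200", ] <- 5L    # constant expression
  a3 <- score_adjacencies(cells0, fx$truth$tf_ids, seed = 3,
                          targets = "G0200", num_trees = 20)
  expect_true(all(a3$importance == 0))
  expect_error(score_adjacencies(fx$cells, "nope", seed = 1), "row")
})

test_that("motif pruning keeps top-k supported targets only", {
  adj <- data.frame(tf = "TF1", target = paste0("g", 1:6),
                    importance = c(10, 9, 8, 7, 6, 5),
                    rho = c(0.5, 0.4, -0.3, 0.2, 0.1, 0.9),
                    run_seed = 1)
  sup <- motif_support(data.frame(tf = "TF1",
                                  gene = c("g1", "g3", "g4", "g6"),
                                  supported = TRUE))
  rs <- prune_by_motif(adj, sup, top_k_per_tf = 4)
  # top-4 by importance: g1..g4; supported among them: g1, g3, g4
  expect_setequal(rs[["TF1(+)"]]$targets, c("g1", "g4"))
  expect_setequal(rs[["TF1(-)"]]$targets, "g3")

  all_sup <- motif_support(data.frame(tf = "TF1", gene = paste0("g", 1:6)))
  rs2 <- prune_by_motif(adj, all_sup, top_k_per_tf = 4)
  expect_setequal(unlist(lapply(rs2, `[[`, "targets")),
                  paste0("g", 1:4))
})

test_that("consensus requires the regulator in every run and targets in two", {
  mk <- function(targets) as_regulon_set(list(
    "TF1(+)" = regulon("TF1", "activating", targets,
                       provenance = "single_run")))
  runs <- list(mk(c("a", "b")), mk(c("a", "c")), mk(c("a", "b")),
               mk(c("a", "d")), mk(c("a", "b")))
  cons <- consensus_regulons(runs)
  expect_named(cons, "TF1(+)")
  # a: 5 runs, b: 3 runs, c and d: 1 run each
  expect_setequal(cons[["TF1(+)"]]$targets, c("a", "b"))
  expect_equal(unname(cons[["TF1(+)"]]$support_runs[c("a", "b")]), c(5L, 3L))

  # regulator missing from one run -> excluded
  runs4 <- runs
  runs4[[3]] <- as_regulon_set(list())
  expect_length(consensus_regulons(runs4), 0)

  # identical runs -> consensus equals a single run with full support
  same <- replicate(5, mk(c("x", "y")), simplify = FALSE)
  cs <- consensus_regulons(same)
  expect_setequal(cs[["TF1(+)"]]$targets, c("x", "y"))
  expect_true(all(cs[["TF1(+)"]]$support_runs == 5))

  expect_error(consensus_regulons(list()), "empty")
  expect_error(consensus_regulons(runs[1:4]), "expected 5")
})

test_that("consensus is run-order invariant and monotone in target support", {
  mk <- function(targets) as_regulon_set(list(
    "TF1(+)" = regulon("TF1", "activating", targets,
                       provenance = "single_run")))
  runs <- list(mk(c("a", "b", "c")), mk(c("a", "b")), mk(c("a", "c")),
               mk(c("a")), mk(c("a", "b", "d")))
  c1 <- consensus_regulons(runs)
  c2 <- consensus_regulons(rev(runs))
  expect_identical(c1, c2)
  sizes <- vapply(1:5, function(ms) {
    cs <- consensus_regulons(runs, min_target_runs = ms)
    if (length(cs) == 0) 0L else length(cs[["TF1(+)"]]$targets)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("custom regulons are added alongside, never overwriting", {
  cons <- as_regulon_set(list(
    "TF2(+)" = regulon("TF2", "activating", c("a", "b"),
                       provenance = "consensus")))
  cust <- as_regulon_set(list(
    "TF1(+)" = regulon("TF1", "activating", "z",
                       provenance = "custom_dual_contrast"),
    "TF2(+)" = regulon("TF2", "activating", "w",
                       provenance = "custom_overexpression")))
  merged <- merge_regulon_sources(cons, cust)
  expect_length(merged, 3)
  tf2 <- merged[names(merged) == "TF2(+)"]
  expect_setequal(vapply(tf2, `[[`, character(1), "provenance"),
                  c("consensus", "custom_overexpression"))

  expect_identical(merge_regulon_sources(cons, as_regulon_set(list())),
                   merge_regulon_sources(cons, as_regulon_set(list())))
  expect_length(merge_regulon_sources(cons, as_regulon_set(list())), 1)
  expect_error(merge_regulon_sources(merged, cust), "duplicate")
})

test_that("the planted regulator survives 5-run consensus with planted targets", {
  fx <- grn_fixture()
  targets <- c(fx$truth$edges$target,
               sample(fx$truth$genes$gene_id[fx$truth$genes$role ==
                                               "background"], 60))
  cons <- run_consensus_grn(fx$cells, fx$truth$tf_ids,
                            fx$truth$motif_support, base_seed = 5,
                            targets = targets, num_trees = 30,
                            top_k_per_tf = 50)
  expect_true("TF1(+)" %in% names(cons))
  surv <- cons[["TF1(+)"]]$targets
  planted <- fx$truth$edges$target[fx$truth$edges$sign == 1]
  expect_gte(mean(surv %in% planted), 0.7)
})

test_that("regulon objects enforce their invariants", {
  expect_error(regulon("TF1", "activating", character()), "non-empty")
  expect_error(regulon("TF1", "activating", c("a", "a")), "duplicate")
  expect_error(regulon("TF1", "activating", c("a", "TF1")), "own TF")
  r <- regulon("TF1", "repressing", c("b", "a"), c(2L, 3L))
  expect_identical(r$targets, c("a", "b"))
  expect_identical(unname(r$support_runs), c(3L, 2L))
  expect_equal(regulon_label(r), "TF1(-)")
})
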