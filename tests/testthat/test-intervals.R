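test_that("summit windows are centred, clipped and 200 bp by default", {
  s <- region_set("chr1", c(980, 40), c(1020, 60), summit_offset = c(20, 10))
  w <- summit_windows(s)
  expect_equal(w$start, c(0, 900))
  expect_equal(w$end, c(150, 1100))
  expect_error(summit_windows(region_set("chr1", 0, 100)), "summit")
  expect_error(summit_windows(s, width = 201), "even")
  expect_equal(formals(summit_windows)$width, 200)
})

test_that("merging unions overlapping regions and is idempotent", {
  x <- region_set("chr1", c(900, 1000), c(1100, 1200))
  m <- merge_overlapping(x)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(900, 1200))

  disjoint <- region_set("chr1", c(0, 500), c(100, 600))
  expect_equal(merge_overlapping(disjoint)[, 1:3], disjoint[, 1:3])
  expect_equal(merge_overlapping(m)[, 1:3], m[, 1:3])
})

test_that("merge preserves per-base coverage on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    rs <- random_regions(60)
    m <- merge_overlapping(rs)
    cb1 <- covered_bases(rs)
    cb2 <- covered_bases(m)
    for (ch in names(cb1)) expect_identical(cb2[[ch]], cb1[[ch]])
    # pairwise non-overlapping within chromosomes
    for (ch in unique(m$chrom)) {
      mm <- m[m$chrom == ch, ]
      if (nrow(mm) > 1)
        expect_true(all(mm$start[-1] > mm$end[-nrow(mm)] - 1))
    }
  }
})

test_that("replicated regions follow the per-base support rule", {
  a <- region_set("chr1", 100, 200)
  same <- replicated_regions(list(a, a), min_support = 2)
  expect_equal(same[, 1:3], a[, 1:3])

  b <- region_set("chr1", 500, 600)
  expect_equal(nrow(replicated_regions(list(b, a, a), min_support = 2)), 1)
  expect_error(replicated_regions(list(), 1), "non-empty")

  # brute-force per-base counting oracle on partial overlaps
  for (seed in 1:5) {
    set.seed(seed)
    reps <- lapply(1:3, function(i) random_regions(25))
    for (ms in 1:3) {
      got <- replicated_regions(reps, ms)
      support <- list()
      for (r in reps) {
        cb <- covered_bases(r)
        for (ch in names(cb)) {
          if (is.null(support[[ch]])) support[[ch]] <- integer(2000)
          support[[ch]][seq_along(cb[[ch]])] <-
            support[[ch]][seq_along(cb[[ch]])] + cb[[ch]]
        }
      }
      want <- covered_bases(got)
      for (ch in names(support)) {
        expect_identical(
          which(support[[ch]] >= ms),
          if (is.null(want[[ch]])) integer(0) else which(want[[ch]])
        )
      }
    }
  }
})

test_that("class-unique regions exclude any cross-class overlap", {
  sets <- list(A = region_set("chr1", c(0, 1000), c(100, 1100)),
               B = region_set("chr1", c(99, 5000), c(300, 5100)))
  u <- class_unique_regions(sets)
  # [0,100) shares base 99 with B's first region -> excluded
  expect_equal(u$A$start, 1000)
  expect_equal(u$B$start, 5000)

  ident <- list(A = region_set("chr1", 0, 50), B = region_set("chr1", 0, 50))
  u2 <- class_unique_regions(ident)
  expect_equal(nrow(u2$A) + nrow(u2$B), 0)
  expect_error(class_unique_regions(sets["A"]), "2 classes")

  # oracle + pairwise disjointness on random instances
  for (seed in 1:4) {
    set.seed(seed)
    sets <- list(A = random_regions(30), B = random_regions(30),
                 C = random_regions(30))
    u <- class_unique_regions(sets)
    for (nm in names(sets)) {
      others <- do.call(rbind, lapply(sets[setdiff(names(sets), nm)],
                                      function(x) x[, 1:3]))
      keep_oracle <- vapply(seq_len(nrow(sets[[nm]])), function(i) {
        r <- sets[[nm]][i, ]
        !any(others$chrom == r$chrom & others$start < r$end &
               others$end > r$start)
      }, logical(1))
      expect_equal(u[[nm]][, 1:3],
                   sets[[nm]][keep_oracle, 1:3], ignore_attr = TRUE)
    }
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      x <- u[[pair[1]]]; y <- u[[pair[2]]]
      if (nrow(x) && nrow(y)) {
        ov <- outer(seq_len(nrow(x)), seq_len(nrow(y)), function(i, j)
          x$chrom[i] == y$chrom[j] & x$start[i] < y$end[j] &
            x$end[i] > y$start[j])
        expect_false(any(ov))
      }
    }
  }
})

test_that("TSS distance follows the half-open boundary convention", {
  g <- list(chrom = "chr1", tss = 50)
  expect_equal(distance_to_tss(list(chrom = "chr1", start = 0, end = 200), g),
               0)
  r <- list(chrom = "chr1", start = 0, end = 200)
  expect_equal(distance_to_tss(r, list(chrom = "chr1", tss = 99999)), 99800)
  expect_equal(distance_to_tss(r, list(chrom = "chr2", tss = 10)), Inf)
  expect_equal(distance_to_tss(r, list(chrom = "chr1", tss = 200)), 1)

  # vectorized min distance agrees with the scalar definition
  set.seed(1)
  rs <- random_regions(40)
  ann <- gene_annotation(paste0("g", 1:30),
                         sample(c("chrA", "chrB"), 30, replace = TRUE),
                         sample(c("+", "-"), 30, replace = TRUE),
                         sample.int(1200, 30))
  d <- min_peak_distance(ann, rs)
  for (i in seq_len(nrow(ann))) {
    want <- min(vapply(seq_len(nrow(rs)), function(j)
      distance_to_tss(rs[j, ], ann[i, ]), numeric(1)))
    expect_equal(unname(d[ann$gene_id[i]]), want)
  }
})

test_that("region annotation categories honour inclusive thresholds", {
  ann <- gene_annotation("g1", "chr1", "+", 10000)
  rs <- region_set("chr1",
                   c(9950, 11000, 20000, 20001, 5e6),
                   c(10050, 11100, 20100, 20101, 5e6 + 100))
  # distances: 0 (TSS inside), 1000 (= window, inclusive), 10000
  # (= 10x window, inclusive), 10001 (just past), and far away
  got <- annotate_regions(rs, ann, promoter_window = 1000)
  expect_equal(got, c("promoter", "promoter", "proximal", "distal", "distal"))
  expect_error(annotate_regions(rs, ann[0, ], 1000), "empty")
})

test_that("GTF transcript records collapse to most-upstream gene TSSs", {
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp))
  lines <- c(
    'chr1\tsrc\ttranscript\t101\t500\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tsrc\ttranscript\t201\t600\t.\t+\t.\tgene_id "gA"; transcript_id "tA2";',
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t-\t.\tgene_id "gB"; transcript_id "tB1";',
    'chr1\tsrc\ttranscript\t1501\t2500\t.\t-\t.\tgene_id "gB"; transcript_id "tB2";')
  writeLines(lines, tmp)
  ann <- read_gtf_tss(tmp)
  expect_equal(ann$tss[ann$gene_id == "gA"], 100)   # 0-based start
  expect_equal(ann$tss[ann$gene_id == "gB"], 2499)  # most upstream on '-'
})
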