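#' Simulation configuration
#'
#' Default parameters of the synthetic study: a single graded regulator in
#' wild-type mesoderm, a planted signed regulon (300 activated + 300
#' repressed targets among 3,000 genes), NB counts with dispersion
#' `variance = mu + phi * mu^2`, knockout cells with the regulator ablated,
#' summit-centred peaks near true-target TSSs, and a 3-replicate
#' short-induction bulk experiment with planted dox confounders.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 3000,
    tf_names = "TF1",
    n_activated = 300,
    n_repressed = 300,
    beta_range = c(0.5, 2),          # log2 effect at full regulator activity
    target_mu_range = c(1.5, 10),    # log-uniform baseline means (counts)
    background_mu_range = c(0.3, 8),
    n_housekeeping = 20,             # high, stable genes anchoring size factors
    housekeeping_mu_range = c(30, 80),
    phi = 0.2,                       # NB dispersion, recycled per gene
    tf_mu = 4,                       # regulator baseline mean
    tf_beta = 3,                     # regulator's own expression gradient
    cell_groups = data.frame(
      genotype = c("WT", "KO", "WT", "KO"),
      cell_type = c("mesoderm", "mesoderm", "endoderm", "endoderm"),
      n = c(2000, 2000, 400, 400),
      stringsAsFactors = FALSE),
    condition = "CTRL",
    day = 7.5,
    libsize_sigma = 0.3,             # log-normal size-factor spread
    n_chromosomes = 2,
    gene_spacing = 250000,           # bp between adjacent TSSs
    window = 100000,                 # peak-to-TSS proximity window (bp)
    peak_width = 200,
    proximal_peak_fraction = 0.9,
    decoy_peak_count = 500,
    motif_support_background_rate = 0.05,
    bulk_replicates = 3,
    early_target_fraction = 0.5,
    n_confounder = 50,
    confounder_log2fc = 1,
    bulk_depth_factor = 50,          # bulk mean = depth factor x baseline mean
    bulk_phi = 0.01,
    bulk_libsize_sigma = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop2("unknown config fields: ",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the planted ground truth
#'
#' Draws the planted network (signed TF->target edges with log2 effects,
#' per-gene baseline means and dispersions) together with a synthetic
#' genome in which genes are spaced so that default proximity windows of
#' adjacent genes never overlap, and a boolean motif-support table covering
#' all true targets plus a background rate of decoy support.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A `planted_network` list with `genes`, `edges`, `annotation`,
#'   `genome`, `motif_support`, `tf_ids`, `config` and `seed`.
#' @export
generate_truth <- function(config = sim_config(), seed = 1) {
  n_tf <- length(config$tf_names)
  if (n_tf < 1) stop2("config must name at least one TF")
  if (config$n_activated < 10 || config$n_repressed < 10)
    stop2("need at least 10 targets per sign")
  n_special <- n_tf + config$n_activated + config$n_repressed +
    config$n_housekeeping
  if (config$n_genes < n_special)
    stop2("config requests more targets than available genes (",
          n_special, " > ", config$n_genes, ")")
  with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(config$n_genes))
    ids[seq_len(n_tf)] <- config$tf_names
    role <- rep("background", config$n_genes)
    role[seq_len(n_tf)] <- "tf"
    pool <- sample(which(role == "background"))
    act <- pool[seq_len(config$n_activated)]
    rep_ <- pool[config$n_activated + seq_len(config$n_repressed)]
    hk <- pool[config$n_activated + config$n_repressed +
                 seq_len(config$n_housekeeping)]
    role[act] <- "activated"; role[rep_] <- "repressed"
    role[hk] <- "housekeeping"

    log_unif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
    mu <- log_unif(config$n_genes, config$background_mu_range)
    mu[role %in% c("activated", "repressed")] <-
      log_unif(sum(role %in% c("activated", "repressed")),
               config$target_mu_range)
    mu[role == "housekeeping"] <-
      log_unif(config$n_housekeeping, config$housekeeping_mu_range)
    mu[role == "tf"] <- config$tf_mu
    phi <- rep_len(config$phi, config$n_genes)

    # genome: genes laid out in id order, evenly split across chromosomes
    chrom_of <- rep(paste0("chr", seq_len(config$n_chromosomes)),
                    each = ceiling(config$n_genes / config$n_chromosomes),
                    length.out = config$n_genes)
    idx_in_chrom <- stats::ave(seq_len(config$n_genes), chrom_of,
                               FUN = seq_along)
    tss <- idx_in_chrom * config$gene_spacing
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genome <- data.frame(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      length = (tapply(idx_in_chrom, chrom_of, max) + 2) * config$gene_spacing,
      stringsAsFactors = FALSE)
    rownames(genome) <- NULL

    genes <- data.frame(gene_id = ids, role = role, chrom = chrom_of,
                        strand = strand, tss = tss, baseline_mu = mu,
                        phi = phi, stringsAsFactors = FALSE)
    tf1 <- config$tf_names[1]
    edges <- data.frame(
      tf = tf1,
      target = c(ids[act], ids[rep_]),
      sign = rep(c(1, -1), c(length(act), length(rep_))),
      beta = runif(length(act) + length(rep_),
                   config$beta_range[1], config$beta_range[2]),
      stringsAsFactors = FALSE)

    support <- do.call(rbind, lapply(config$tf_names, function(tf) {
      true_t <- edges$target[edges$tf == tf]
      others <- setdiff(ids, c(tf, true_t))
      bg <- others[runif(length(others)) <
                     config$motif_support_background_rate]
      data.frame(tf = tf, gene = c(true_t, bg), supported = TRUE,
                 stringsAsFactors = FALSE)
    }))

    structure(list(
      genes = genes,
      edges = edges,
      tf_ids = config$tf_names,
      annotation = gene_annotation(ids, chrom_of, strand, tss),
      genome = genome,
      motif_support = motif_support(support),
      config = config,
      seed = seed), class = "planted_network")
  })
}

#' Simulate single-cell counts under the planted network
#'
#' Counts are NB draws with mean
#' `mu_gc = sf_c * baseline_mu_g * 2^(sign * beta * a_c)`, where the
#' regulator activity `a_c` is uniform on `[0, 1]` in wild-type mesoderm
#' and 0 elsewhere, and `sf_c` is a log-normal library-size factor. The
#' regulator's own expression follows the same gradient
#' (`tf_mu * 2^(tf_beta * a_c)`); knockout cells have regulator counts
#' forced to zero.
#'
#' @param truth A `planted_network` from [generate_truth()].
#' @param config A [sim_config()]; defaults to the truth's config.
#' @param seed Integer seed.
#' @return A `cell_matrix` list with integer `counts` (gene x cell) and
#'   aligned `cell_meta` (genotype, cell_type, condition, day, activity,
#'   size_factor).
#' @export
simulate_cells <- function(truth, config = truth$config, seed = 1) {
  grp <- config$cell_groups
  if (any(grp$n <= 0)) stop2("each cell group needs a positive cell count")
  with_seed(seed, {
    n_cells <- sum(grp$n)
    genotype <- rep(grp$genotype, grp$n)
    cell_type <- rep(grp$cell_type, grp$n)
    activity <- ifelse(genotype == "WT" & cell_type == "mesoderm",
                       runif(n_cells), 0)
    sf <- rlnorm(n_cells, meanlog = -config$libsize_sigma^2 / 2,
                 sdlog = config$libsize_sigma)
    cell_id <- sprintf("cell%05d", seq_len(n_cells))

    genes <- truth$genes
    G <- nrow(genes)
    # signed log2 effect per gene (0 for non-targets)
    eff <- setNames(numeric(G), genes$gene_id)
    eff[truth$edges$target] <- truth$edges$sign * truth$edges$beta
    is_tf <- genes$role == "tf"
    tf1 <- truth$tf_ids[1]

    counts <- matrix(0L, nrow = G, ncol = n_cells,
                     dimnames = list(genes$gene_id, cell_id))
    block <- 500L
    for (b in seq(1, n_cells, by = block)) {
      jj <- b:min(b + block - 1, n_cells)
      mu <- outer(genes$baseline_mu, sf[jj])
      mu <- mu * 2^(outer(eff, activity[jj]))
      # regulator gradient rides on its own expression
      mu[genes$gene_id == tf1, ] <-
        mu[genes$gene_id == tf1, ] * 2^(config$tf_beta * activity[jj])
      mu[is_tf, genotype[jj] == "KO"] <- 0
      phi <- rep(genes$phi, length(jj))
      x <- numeric(length(mu))
      nbi <- phi >= 1e-12
      if (any(nbi))
        x[nbi] <- rnbinom(sum(nbi), mu = mu[nbi], size = 1 / phi[nbi])
      if (any(!nbi)) x[!nbi] <- rpois(sum(!nbi), mu[!nbi])
      counts[, jj] <- as.integer(x)
    }
    structure(list(
      counts = counts,
      cell_meta = data.frame(cell_id = cell_id, genotype = genotype,
                             cell_type = cell_type,
                             condition = config$condition, day = config$day,
                             activity = activity, size_factor = sf,
                             stringsAsFactors = FALSE)),
      class = "cell_matrix")
  })
}

#' Simulate summit-centred peaks around true-target TSSs
#'
#' A configured fraction of true targets receives one 200-bp summit-centred
#' peak lying entirely within the proximity window `W` of the target's TSS;
#' decoy peaks are placed strictly farther than `W` from every true-target
#' TSS. The returned object reports which genes pass a `W`-window filter:
#' exactly the proximal-peak targets plus any gene whose TSS incidentally
#' falls within `W` of a decoy.
#'
#' @inheritParams simulate_cells
#' @return A `peak_simulation` list with `peaks` (a [region_set()]),
#'   `proximal_targets`, `incidental_genes`, `passing_genes` and `window`.
#' @export
simulate_peaks <- function(truth, config = truth$config, seed = 1) {
  W <- config$window
  half <- config$peak_width / 2
  if (W >= min(truth$genome$length))
    stop2("proximity window is larger than a chromosome")
  with_seed(seed, {
    genes <- truth$genes
    edges <- truth$edges
    chrom_len <- setNames(truth$genome$length, truth$genome$chrom)

    pick_per_sign <- function(sgn) {
      t <- edges$target[edges$sign == sgn]
      sample(t, round(config$proximal_peak_fraction * length(t)))
    }
    proximal <- c(pick_per_sign(1), pick_per_sign(-1))
    gi <- match(proximal, genes$gene_id)
    # summit uniform within W - half of the TSS keeps all bases within W
    lo <- pmax(half, genes$tss[gi] - (W - half))
    hi <- pmin(chrom_len[genes$chrom[gi]] - half, genes$tss[gi] + (W - half))
    summit <- floor(runif(length(gi), lo, hi))
    prox_rs <- data.frame(chrom = genes$chrom[gi], start = summit - half,
                          end = summit + half,
                          name = paste0("peak_", proximal),
                          stringsAsFactors = FALSE)

    target_ann <- truth$annotation[truth$annotation$gene_id %in%
                                     edges$target, , drop = FALSE]
    decoys <- list(); got <- 0; tries <- 0
    while (got < config$decoy_peak_count && tries < 200) {
      tries <- tries + 1
      need <- config$decoy_peak_count - got
      ch <- sample(truth$genome$chrom, 2 * need, replace = TRUE,
                   prob = truth$genome$length)
      summit <- floor(runif(2 * need, half, chrom_len[ch] - half))
      cand <- region_set(ch, summit - half, summit + half)
      d <- region_tss_distance(cand, target_ann)
      ok <- which(d > W)
      take <- head(ok, need)
      if (length(take)) {
        got <- got + length(take)
        decoys[[length(decoys) + 1]] <- cand[take, , drop = FALSE]
      }
    }
    if (got < config$decoy_peak_count)
      stop2("could not place the requested number of decoy peaks")
    decoy_df <- do.call(rbind, decoys)
    decoy_df$name <- paste0("decoy_", seq_len(nrow(decoy_df)))

    peaks <- region_set(c(prox_rs$chrom, decoy_df$chrom),
                        c(prox_rs$start, decoy_df$start),
                        c(prox_rs$end, decoy_df$end),
                        name = c(prox_rs$name, decoy_df$name),
                        summit_offset = half)
    dist <- min_peak_distance(truth$annotation, peaks)
    passing <- names(dist)[dist <= W]
    structure(list(peaks = peaks,
                   proximal_targets = sort(proximal),
                   incidental_genes = sort(setdiff(passing, proximal)),
                   passing_genes = sort(passing),
                   window = W), class = "peak_simulation")
  })
}

#' Simulate the short-induction bulk experiment
#'
#' Four arms with `bulk_replicates` samples each: `induced` and `control`
#' (the transgene line with and without induction) and
#' `confounder_induced` / `confounder_control` (a line without the
#' transgene, isolating the inducer's own effect). A configured fraction of
#' true targets responds at induction (shifted by `sign * beta`); planted
#' confounder genes shift identically in both induced arms.
#'
#' @inheritParams simulate_cells
#' @return A `bulk_experiment` list with integer `counts` (gene x sample),
#'   `sample_meta` (arm, replicate), `early_targets` and `confounder_genes`.
#' @export
simulate_induction_bulk <- function(truth, config = truth$config, seed = 1) {
  f <- config$early_target_fraction
  if (f < 0 || f > 1) stop2("early_target_fraction must be in [0, 1]")
  with_seed(seed, {
    genes <- truth$genes
    edges <- truth$edges
    pick <- function(sgn) {
      t <- edges$target[edges$sign == sgn]
      sample(t, round(f * length(t)))
    }
    early <- c(pick(1), pick(-1))
    bg <- genes$gene_id[genes$role == "background"]
    confounders <- sample(bg, min(config$n_confounder, length(bg)))

    arms <- c("induced", "control", "confounder_induced",
              "confounder_control")
    reps <- config$bulk_replicates
    arm <- rep(arms, each = reps)
    sample_id <- paste0(arm, "_rep", rep(seq_len(reps), times = length(arms)))

    base_mu <- genes$baseline_mu * config$bulk_depth_factor
    eff <- setNames(numeric(nrow(genes)), genes$gene_id)
    eff[edges$target[edges$target %in% early]] <-
      (edges$sign * edges$beta)[edges$target %in% early]
    conf_eff <- setNames(numeric(nrow(genes)), genes$gene_id)
    conf_eff[confounders] <- config$confounder_log2fc

    n_samp <- length(arm)
    lib <- rlnorm(n_samp, meanlog = -config$bulk_libsize_sigma^2 / 2,
                  sdlog = config$bulk_libsize_sigma)
    counts <- matrix(0L, nrow = nrow(genes), ncol = n_samp,
                     dimnames = list(genes$gene_id, sample_id))
    for (j in seq_len(n_samp)) {
      mu <- base_mu * lib[j]
      if (arm[j] == "induced") mu <- mu * 2^eff
      if (arm[j] %in% c("induced", "confounder_induced"))
        mu <- mu * 2^conf_eff
      counts[, j] <- as.integer(rnbinom(nrow(genes), mu = mu,
                                        size = 1 / config$bulk_phi))
    }
    structure(list(counts = counts,
                   sample_meta = data.frame(sample_id = sample_id, arm = arm,
                                            replicate = rep(seq_len(reps),
                                                            length(arms)),
                                            stringsAsFactors = FALSE),
                   early_targets = sort(early),
                   confounder_genes = sort(confounders)),
              class = "bulk_experiment")
  })
}

#' Simulate motif hits over labelled region sets
#'
#' Bernoulli motif hits per (motif, region): at the motif's background rate
#' everywhere except in its configured enriched class, where the rate is
#' multiplied by `fold` (capped at 1).
#'
#' @param class_sets Named list of [region_set()]s with region `name`s.
#' @param motifs Data frame with columns `motif_id`, `p_bg` and optional
#'   `enriched_class`, `fold`.
#' @param seed Integer seed.
#' @return A `motif_hit_table`.
#' @export
simulate_motif_hits <- function(class_sets, motifs, seed = 1) {
  if (is.null(motifs$enriched_class)) motifs$enriched_class <- NA_character_
  if (is.null(motifs$fold)) motifs$fold <- 1
  with_seed(seed, {
    rows <- list()
    for (m in seq_len(nrow(motifs))) {
      for (cl in names(class_sets)) {
        rate <- motifs$p_bg[m] *
          if (!is.na(motifs$enriched_class[m]) &&
              identical(cl, motifs$enriched_class[m])) motifs$fold[m] else 1
        rate <- min(rate, 1)
        ids <- class_sets[[cl]]$name
        hit <- runif(length(ids)) < rate
        if (any(hit))
          rows[[length(rows) + 1]] <- data.frame(
            motif_id = motifs$motif_id[m], region_id = ids[hit],
            stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(motif_id = character(), region_id = character())
    motif_hit_table(hits, setNames(motifs$p_bg, motifs$motif_id))
  })
}

#' MAD-based low-count cell filtering
#'
#' Removes cells whose log-scale total count falls more than `k` median
#' absolute deviations (scaled, as in standard outlier calling) below the
#' median, or whose total is below an absolute floor. When the MAD is 0
#' (degenerate spread) no cell is removed by the MAD rule; the floor still
#' applies.
#'
#' @param cells A `cell_matrix`.
#' @param k MAD multiplier (> 0).
#' @param floor Minimum total count.
#' @return The filtered `cell_matrix`, with removed cell ids in
#'   `attr(, "removed")`.
#' @export
mad_filter_cells <- function(cells, k = 3, floor = 500) {
  if (k <= 0) stop2("`k` must be > 0")
  counts <- cells$counts
  if (is.null(counts) || ncol(counts) == 0) stop2("empty cell matrix")
  totals <- colSums(counts)
  lt <- log1p(totals)
  m <- mad(lt)
  low <- if (m > 0) lt < median(lt) - k * m else rep(FALSE, length(lt))
  drop <- low | totals < floor
  out <- list(counts = counts[, !drop, drop = FALSE],
              cell_meta = cells$cell_meta[!drop, , drop = FALSE])
  rownames(out$cell_meta) <- NULL
  class(out) <- "cell_matrix"
  attr(out, "removed") <- colnames(counts)[drop]
  out
}
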