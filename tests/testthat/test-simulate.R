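test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(duplication_blocks = list(c(70000L, 2L)),
                          sequence_length = 60000), "longer than sequence")
  expect_error(sim_config(knockdown_fold = 1), "knockdown_fold")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  expect_error(simulate_pirna_reads(g$truth, cfg, "mystery"), "arg")
})

test_that("the same seed reproduces the genome and truth exactly", {
  cfg <- tiny_sim_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  # a different seed changes the sequence
  g3 <- simulate_genome(tiny_sim_config(seed = 7L))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("RNG substreams make samples independent of generation order", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  direct <- simulate_mark_fragments(g$truth, cfg, "H3K27me3")
  # generating other data first must not perturb this track
  invisible(simulate_pirna_reads(g$truth, cfg, "control"))
  invisible(simulate_mark_fragments(g$truth, cfg, "H3K9me3"))
  again <- simulate_mark_fragments(g$truth, cfg, "H3K27me3")
  expect_identical(direct$counts, again$counts)
  expect_identical(direct$replicates, again$replicates)
})

test_that("duplicated blocks create low-mappability bins; the rest stays unique", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  mt <- compute_mappability(g$genome, 26L)
  bins <- bin_mappability(tile_genome(g$genome, cfg$bin_size), mt)
  dup_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    g$duplicated_regions$chrom,
    IRanges::IRanges(g$duplicated_regions$start + 1,
                     g$duplicated_regions$end)))
  in_dup <- suppressWarnings(IRanges::overlapsAny(
    GenomicRanges::GRanges(bins$chrom,
                           IRanges::IRanges(bins$start + 1, bins$end)),
    dup_gr))
  expect_true(all(bins$mappability[in_dup] < 0.2))
  expect_true(all(bins$mappability[!in_dup] > 0.9))

  # with no duplication blocks every interior n-mer is unique
  g0 <- simulate_genome(tiny_sim_config(duplication_blocks = list()))
  mt0 <- compute_mappability(g0$genome, 26L)
  expect_true(all(unlist(mt0$unique_start)))
})

test_that("with no enrichment, marked and unmarked bins are indistinguishable", {
  cfg <- sim_config(seed = 5L, n_sequences = 2L, sequence_length = 1.25e6,
                    bin_size = 500L, enrichment_fold = 1,
                    duplication_blocks = list())
  g <- simulate_genome(cfg)
  sim <- simulate_mark_fragments(g$truth, cfg, "H3K9me3", n_replicates = 1L)
  marked <- g$truth$mark_state %in% c("K9only", "both") &
    g$truth$chrom %in% c("chr1", "chr2")
  on_chrom <- g$truth$chrom %in% c("chr1", "chr2")
  p <- stats::wilcox.test(sim$counts[marked & on_chrom, 1],
                          sim$counts[!marked & on_chrom, 1])$p.value
  expect_gt(p, 0.01)
})

test_that("marked-bin counts follow the configured negative-binomial mean", {
  cfg <- sim_config(seed = 8L, n_sequences = 2L, sequence_length = 1.25e6,
                    bin_size = 500L, duplication_blocks = list(),
                    mark_state_props = c(none = 0, K9only = 0, K27only = 0,
                                         both = 1))
  g <- simulate_genome(cfg)
  sim <- simulate_mark_fragments(g$truth, cfg, "H3K27me3")
  marked <- g$truth$mark_state == "both"
  x <- as.numeric(sim$counts[marked, ])        # >= 10,000 marked draws
  mu <- cfg$mark_background_mean * cfg$enrichment_fold
  se <- sqrt((mu + cfg$nb_dispersion * mu^2) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # background track stays at the background mean
  bg <- as.numeric(sim$background$counts)
  se_bg <- sqrt((20 + 0.1 * 400) / length(bg))
  expect_lt(abs(mean(bg) - cfg$mark_background_mean), 3 * se_bg)
})

test_that("knockdown rules rescale expected piRNA means exactly", {
  cfg <- tiny_sim_config(pirna_mean = 80, knockdown_fold = 8)
  g <- simulate_genome(cfg)
  tt <- g$truth
  mu <- dualmark:::.pirna_mu
  ez <- mu(tt, cfg, "EzKD", "+")
  ctl <- mu(tt, cfg, "control", "+")
  sel <- tt$dependency_class == "Ez_dep"
  expect_equal(ez[sel], rep(10, sum(sel)))     # 80 / 8
  expect_equal(ez[tt$dependency_class == "Kipf_dep"],
               ctl[tt$dependency_class == "Kipf_dep"])
  expect_equal(ez[tt$dependency_class == "gain_on_EzKD"],
               ctl[tt$dependency_class == "gain_on_EzKD"] * cfg$gain_fold)
  # doubleKD applies both rules; both-dependent bins are divided twice
  dbl <- mu(tt, cfg, "doubleKD", "+")
  expect_equal(dbl[tt$dependency_class == "both_dep"],
               rep(80 / 64, sum(tt$dependency_class == "both_dep")))
  # rhiKD divides every dual-strand bin and leaves the rest alone
  rk <- mu(tt, cfg, "rhiKD", "+")
  dual <- tt$cluster_label == "dual_strand"
  expect_equal(rk[dual], ctl[dual] / 8)
  expect_equal(rk[!dual], ctl[!dual])
  # unistrand bins emit on their annotated strand only, in every condition
  uni <- tt$cluster_label == "unistrand" & tt$strand == "+"
  expect_equal(rk[uni], rep(cfg$unistrand_mean, sum(uni)))
  expect_equal(mu(tt, cfg, "rhiKD", "-")[uni],
               rep(cfg$pirna_background_mean, sum(uni)))
})

test_that("dual-strand bins carry nonzero control piRNA on both strands", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  sim <- simulate_pirna_reads(g$truth, cfg, "control")
  dual <- g$truth$cluster_label == "dual_strand"
  expect_true(all(rowSums(sim$counts_plus[dual, , drop = FALSE]) > 0))
  expect_true(all(rowSums(sim$counts_minus[dual, , drop = FALSE]) > 0))
  # dependency classes only occur on dual-strand bins
  expect_true(all(g$truth$cluster_label[g$truth$dependency_class != "none"]
                  == "dual_strand"))
})

test_that("re-quantifying placed fragments recovers the drawn counts exactly", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  bins <- g$truth[, c("chrom", "start", "end", "bin_id")]
  sim <- simulate_mark_fragments(g$truth, cfg, "H3K9me3")
  for (r in seq_along(sim$replicates)) {
    counts <- count_fragments(bins, sim$replicates[[r]], 0.5)
    expect_equal(as.integer(counts), as.integer(sim$counts[, r]))
  }
  pir <- simulate_pirna_reads(g$truth, cfg, "control", n_replicates = 1L)
  expect_equal(as.integer(count_fragments(bins, pir$replicates[[1]], 0.5, "+")),
               as.integer(pir$counts_plus[, 1]))
  expect_equal(as.integer(count_fragments(bins, pir$replicates[[1]], 0.5, "-")),
               as.integer(pir$counts_minus[, 1]))
})

test_that("truth marginals match the configured proportions within binomial error", {
  cfg <- sim_config(seed = 3L, n_sequences = 2L, sequence_length = 1e6,
                    duplication_blocks = list())
  g <- simulate_genome(cfg)
  on_chrom <- g$truth$chrom %in% c("chr1", "chr2")
  n <- sum(on_chrom)
  for (st in names(cfg$mark_state_props)) {
    p <- cfg$mark_state_props[[st]]
    obs <- mean(g$truth$mark_state[on_chrom] == st)
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("fixture files round-trip and regenerate byte-identically", {
  cfg <- tiny_sim_config()
  co <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(co, d1)
  write_fixture(simulate_cohort(cfg), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)

  # BED intervals are 0-based half-open within bounds
  seqlens <- read_chrom_sizes(file.path(d1, "chrom.sizes"))
  fr <- read_fragments_bed(file.path(d1, "H3K9me3_rep1.bed"))
  expect_true(all(fr$start >= 0))
  expect_true(all(fr$end <= seqlens[fr$chrom]))
  expect_true(all(fr$start < fr$end))

  # re-read fragments reproduce the in-memory counts
  bins <- co$truth[, c("chrom", "start", "end", "bin_id")]
  expect_equal(as.integer(count_fragments(bins, fr, 0.5)),
               as.integer(co$marks$H3K9me3$counts[, 1]))

  # configuration round-trips through its YAML serialization
  cfg_back <- read_sim_config(file.path(d1, "config.yaml"))
  expect_equal(unclass(cfg_back), unclass(cfg), tolerance = 0)

  # a path below an existing regular file is unwritable
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  expect_error(suppressWarnings(write_fixture(co, file.path(blocker, "sub"))),
               "cannot write")
})
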