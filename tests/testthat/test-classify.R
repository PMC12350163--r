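test_that("ROC/AUC handles separation, ties and the worked four-bin case", {
  r <- roc_auc(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(utils::tail(r$tpr, 1), 1)
  expect_equal(r$fpr[1], 0)

  r <- roc_auc(rep(1, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(r$auc, 0.5)                    # all tied: single diagonal
  expect_equal(length(r$thresholds), 1L)

  # 3 of 4 positive-negative pairs concordant
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)

  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic on random data", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- sample(1:8, n, TRUE) + sample(c(0, 0.5), n, TRUE) # many ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc_rank(scores, labels))
  }
})

test_that("AUC flips under score negation and is rank-invariant", {
  set.seed(78)
  scores <- rnorm(50)
  labels <- c(rep(TRUE, 20), rep(FALSE, 30))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a)
  expect_equal(roc_auc(exp(2 * scores), labels)$auc, a) # monotone transform
  # agreement with an established ROC implementation
  pr <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  expect_equal(a, as.numeric(pROC::auc(pr)))
})

test_that("mark combination is the element-wise mean on matched bins", {
  expect_equal(combine_marks(c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(combine_marks(2, 0), 1)
  expect_error(combine_marks(1:3, 1:2), "mismatched")
  expect_error(combine_marks(c(x = 1), c(y = 1)), "names")
})

test_that("consensus peaks merge across replicates and enforce support", {
  p <- data.frame(chrom = "c", start = 100, end = 200)
  out <- consensus_peaks(list(p, p), min_support = 2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 2L)

  out <- consensus_peaks(list(p, data.frame(chrom = "c", start = 500, end = 600),
                              data.frame(chrom = "c", start = 510, end = 610)),
                         min_support = 2)
  expect_equal(out$start, 500)               # singleton peak dropped
  expect_equal(out$end, 610)

  # chained overlaps A-B, B-C (A and C disjoint) merge with support 3
  a <- data.frame(chrom = "c", start = 0, end = 100)
  b <- data.frame(chrom = "c", start = 90, end = 200)
  c_ <- data.frame(chrom = "c", start = 190, end = 300)
  out <- consensus_peaks(list(a, b, c_), min_support = 2)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end, out$support), c(0, 300, 3))

  # single replicate keeps everything; consensus of consensus is stable
  out1 <- consensus_peaks(list(p))
  expect_equal(nrow(out1), 1L)
  twice <- consensus_peaks(list(out, out), min_support = 2)
  expect_equal(twice[, c("chrom", "start", "end")],
               out[, c("chrom", "start", "end")])
})

test_that("bin presence uses >= 1 bp overlap with half-open semantics", {
  bins <- tile_genome(c(c = 2000), 1000)
  pres <- bin_presence(bins, data.frame(chrom = "c", start = 500, end = 600))
  expect_equal(unname(pres), c(TRUE, FALSE))
  # peak ending exactly at the bin start does not touch it
  pres <- bin_presence(bins, data.frame(chrom = "c", start = 900, end = 1000))
  expect_equal(unname(pres), c(TRUE, FALSE))
  pres <- bin_presence(bins, data.frame(chrom = "c", start = 1000, end = 1001))
  expect_equal(unname(pres), c(FALSE, TRUE))
})

test_that("the worked 2x2 table gives OR 36 and the exact two-sided p", {
  a <- c(rep(TRUE, 40), rep(FALSE, 65))
  b <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 60))
  ot <- overlap_enrichment(a, b)
  expect_equal(c(ot$a, ot$b, ot$c, ot$d), c(30, 10, 5, 60))
  expect_equal(ot$odds_ratio, 36)
  expect_equal(ot$p_value, oracle_fisher_p(30, 10, 5, 60), tolerance = 1e-12)
  expect_equal(ot$p_value,
               stats::fisher.test(matrix(c(30, 5, 10, 60), 2))$p.value)
})

test_that("Fisher p equals the exhaustive oracle across small-margin tables", {
  for (a in c(0, 1, 3, 7)) for (b in c(0, 2, 9)) for (c_ in c(0, 4, 11))
    for (d in c(1, 6, 20)) {
      if (a + b + c_ + d == 0) next
      expect_lt(abs(fisher_exact_p(a, b, c_, d) -
                    oracle_fisher_p(a, b, c_, d)), 1e-12)
    }
})

test_that("Haldane correction engages exactly when a cell is empty", {
  ot <- overlap_enrichment(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_true(ot$haldane)
  expect_equal(ot$odds_ratio, (2.5 * 1.5) / (0.5 * 0.5))
})

test_that("independent presence vectors give a null OR", {
  set.seed(99)
  a <- runif(10000) < 0.3
  b <- runif(10000) < 0.4
  ot <- overlap_enrichment(a, b)
  expect_gt(ot$odds_ratio, 0.8)
  expect_lt(ot$odds_ratio, 1.25)
  expect_gt(ot$p_value, 0.01)
})

test_that("stratified ORs give one table per stratum over the same universe", {
  set.seed(100)
  strata <- sample(c("both", "K9only", "K27only", "neither"), 500, TRUE)
  binding <- runif(500) < ifelse(strata == "both", 0.8, 0.1)
  out <- stratified_enrichment(binding, strata)
  expect_named(out, c("K27only", "K9only", "both", "neither"))
  for (t in out) expect_equal(t$a + t$b + t$c + t$d, 500)
  expect_gt(out$both$odds_ratio, 1)
})

test_that("venn partition counts are exact and sum to the universe", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(FALSE, FALSE, TRUE, FALSE)
  v <- venn_partition(list(A = a, B = b))
  expect_equal(unname(v["A&B"]), 0L)       # disjoint sets
  v <- venn_partition(list(A = c(TRUE, FALSE), B = c(TRUE, TRUE)))
  expect_equal(unname(v["A&!B"]), 0L)      # A inside B
  set.seed(41)
  sets <- lapply(1:3, function(i) runif(200) < 0.4)
  names(sets) <- c("X", "Y", "Z")
  v <- venn_partition(sets)
  expect_equal(sum(v), 200L)
  # brute-force per-element membership enumeration
  key <- apply(do.call(cbind, sets), 1, function(r)
    paste(ifelse(r, names(sets), paste0("!", names(sets))), collapse = "&"))
  expect_equal(unname(v[names(table(key))]), as.integer(table(key)))
  expect_error(venn_partition(rep(sets, 2)), "4")
})

test_that("level grouping builds a zero group plus rank-breakpoint intervals", {
  expect_warning(g <- group_by_level(rep(0, 5)), "nonzero")
  expect_equal(g$group, rep(1L, 5))

  g <- group_by_level(c(0, 0, 1:15))
  expect_equal(nrow(g$breaks), 14L)
  expect_equal(unname(g$sizes["zero"]), 2L)
  # half-open intervals with the top interval closed: 13 singletons + {14,15}
  expect_equal(unname(g$sizes[-1]), c(rep(1L, 13), 2L))

  # heavy ties: fewer groups, none empty, still a partition
  set.seed(13)
  lv <- sample(c(0, 1, 1, 1, 2, 2, 5), 300, TRUE)
  g <- group_by_level(lv)
  expect_true(all(g$group >= 1))
  expect_lt(nrow(g$breaks), 14L)
  expect_true(all(g$sizes[-1] > 0))
  expect_equal(sum(g$sizes), 300L)
  expect_equal(sum(g$group == 1), sum(lv == 0))
})
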