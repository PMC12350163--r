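# Small helper: wrap per-bin control/depleted vectors as one strategy.
one_strategy <- function(control, depleted)
  list(s1 = list(control = cbind(control), depleted = cbind(depleted)))

test_that("fold loss averages replicate means within, then across, strategies", {
  exps <- list(
    A = list(control = cbind(c(80, 10)), depleted = cbind(c(10, 10))),
    B = list(control = cbind(c(50, 20)), depleted = cbind(c(20, 20))))
  fl <- fold_loss(exps, pseudocount = 0)
  expect_equal(fl, c(mean(c(8, 2.5)), 1))
  # replicate averaging inside the arm
  exps2 <- list(A = list(control = cbind(c(60), c(100)), depleted = cbind(c(20), c(20))))
  expect_equal(fold_loss(exps2, 0), 4)
  # ratio-of-means mode
  expect_equal(fold_loss(exps, 0, mode = "ratio_of_means"),
               c((80 + 50) / 2 / 15, 1))
  expect_error(fold_loss(list(), 0), "strategy")
  expect_error(fold_loss(list(A = list(control = cbind(1:2), depleted = cbind(1:2)),
                              B = list(control = cbind(1:3), depleted = cbind(1:3))),
                         0), "bin sets differ")
})

test_that("Rhi dependency requires mean fold-loss above the threshold", {
  dep <- classify_rhi_dependent(
    list(A = list(control = cbind(c(80, 10, 30)), depleted = cbind(c(10, 10, 16)))),
    threshold_fold = 2, pseudocount = 0)
  expect_equal(as.logical(dep), c(TRUE, FALSE, FALSE))
  expect_equal(attr(dep, "fold"), c(8, 1, 1.875))
  # fold-changes 8 and 2.5 across strategies: mean 5.25 > 2
  exps <- list(A = list(control = cbind(80), depleted = cbind(10)),
               B = list(control = cbind(50), depleted = cbind(20)))
  expect_true(as.logical(classify_rhi_dependent(exps, 2, 0)))
})

test_that("with threshold 1 and no pseudocount, single-arm calls reduce to a direct comparison", {
  set.seed(21)
  control <- runif(200, 0, 50)
  depleted <- runif(200, 0, 50)
  dep <- classify_rhi_dependent(one_strategy(control, depleted),
                                threshold_fold = 1, pseudocount = 0)
  expect_equal(as.logical(dep), control > depleted)
  # multi-strategy ratio-of-means marks bins whose mean control exceeds mean depleted
  exps <- list(A = list(control = cbind(control), depleted = cbind(depleted)),
               B = list(control = cbind(rev(control)), depleted = cbind(rev(depleted))))
  dep2 <- classify_rhi_dependent(exps, 1, 0, mode = "ratio_of_means")
  expect_equal(as.logical(dep2),
               (control + rev(control)) / 2 > (depleted + rev(depleted)) / 2)
})

test_that("E(z)/Kipf categories follow the fold thresholds and partition", {
  rhi <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  fe <- c(10, 1, 5, 2, 50)
  fk <- c(1, 10, 5, 2, 50)
  tab <- classify_ez_kipf(rhi, fe, fk, threshold_fold = 4)
  expect_equal(tab$category, c("Ez_dep", "Kipf_dep", "both", "neither"))
  expect_equal(tab$bin, 1:4)                  # non-Rhi-dependent bins excluded
  expect_equal(sort(unique(tab$category)) %in%
                 c("Ez_dep", "Kipf_dep", "both", "neither"), rep(TRUE, 4))
  expect_equal(nrow(tab), sum(rhi))           # exactly one category per bin
  # threshold is inclusive (>= 4-fold mean loss)
  tab4 <- classify_ez_kipf(TRUE, 4, 1, 4)
  expect_equal(tab4$category, "Ez_dep")
})

test_that("peak dependency builds, excludes and splits the high-confidence set", {
  ctl1 <- data.frame(chrom = c("chr1", "chr1", "chr2", "Scaffold_9", "chr2"),
                     start = c(0, 5000, 100, 0, 9000),
                     end = c(1000, 6000, 1100, 500, 10000),
                     fold_enrichment = c(5, 2.9, 4, 8, 6))
  ctl2 <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                     start = c(100, 5100, 150, 9100),
                     end = c(900, 5900, 1000, 9900),
                     fold_enrichment = c(6, 2.5, 5, 7))
  rhikd <- data.frame(chrom = "chr2", start = 9500, end = 9600)
  kipfkd <- data.frame(chrom = "chr1", start = 0, end = 500)
  out <- classify_peaks_kipf(list(ctl1, ctl2), rhikd, kipfkd, min_fold = 3)
  # the 2.9/2.5-fold peak never enters the high-confidence set
  expect_false(any(out$start == 5000))
  expect_equal(out$reason[out$chrom == "Scaffold_9"], "unplaced_contig")
  expect_equal(out$reason[out$start == 9000], "present_in_rhiKD")
  expect_true(all(is.na(out$kipf_class[out$excluded])))
  kept <- out[!out$excluded, ]
  expect_equal(kept$kipf_class[kept$chrom == "chr1"], "independent")
  expect_equal(kept$kipf_class[kept$chrom == "chr2"], "dependent")
  # classes plus exclusions partition the set
  expect_equal(sum(out$excluded) + sum(!is.na(out$kipf_class)), nrow(out))
  expect_error(classify_peaks_kipf(list(ctl1[, 1:3]), rhikd, kipfkd),
               "fold_enrichment")
})

test_that("names without a chr prefix count as unplaced by default", {
  ctl <- data.frame(chrom = c("chr1", "211000022278279", "chrX_rand7"),
                    start = c(0, 0, 0), end = c(100, 100, 100),
                    fold_enrichment = 5)
  out <- classify_peaks_kipf(list(ctl),
                             rhikd = NULL, kipfkd = NULL, min_fold = 3)
  expect_equal(out$excluded[order(out$chrom)],
               c("211000022278279", "chr1", "chrX_rand7") != "chr1")
})

test_that("delta grouping is an equal-size rank partition with mean summaries", {
  d <- stats::setNames(c(12:1), sprintf("b%02d", 1:12))
  res <- delta_group_analysis(d, list(r = d * 2), n_groups = 6)
  expect_equal(as.integer(table(res$group)), rep(2L, 6))
  # group 1 holds the strongest losses (lowest delta)
  expect_equal(sort(names(d)[res$group == 1]), c("b11", "b12"))
  expect_equal(res$summary$mean_delta, c(1.5, 3.5, 5.5, 7.5, 9.5, 11.5))
  expect_equal(res$summary$mean_r, res$summary$mean_delta * 2)
  # responder proportional to delta implies monotone group means
  expect_true(all(diff(res$summary$mean_r) > 0))
})

test_that("delta grouping handles constant input and remainders deterministically", {
  d <- stats::setNames(rep(0, 13), sprintf("b%02d", 1:13))
  res <- delta_group_analysis(d, list(r = rep(1, 13)), n_groups = 6)
  expect_equal(as.integer(table(res$group)), c(3L, 2L, 2L, 2L, 2L, 2L))
  # ties broken by bin id: first group holds b01..b03
  expect_equal(names(d)[res$group == 1], c("b01", "b02", "b03"))
  expect_true(all(is.finite(res$summary$mean_r)))
})

test_that("the percentile restriction keeps high-secondary bins and needs compartments", {
  d <- stats::setNames(rnorm(100), sprintf("b%03d", 1:100))
  secondary <- seq_len(100)
  comp <- rep(c("euchromatin", "heterochromatin"), 50)
  expect_error(delta_group_analysis(d, list(), 6, secondary = secondary),
               "compartment")
  res <- delta_group_analysis(d, list(), n_groups = 2, secondary = secondary,
                              compartment = comp, percentile = 90)
  thr <- stats::quantile(secondary[comp == "euchromatin"], 0.9, names = FALSE)
  expect_equal(res$threshold, thr)
  expect_equal(sort(res$bins), sort(names(d)[secondary > thr]))
})
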