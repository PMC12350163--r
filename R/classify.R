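#' ROC curve and AUC for bin classification
#'
#' Bins are ranked by score (descending); tied scores are grouped at a
#' single threshold, so ties contribute a diagonal segment rather than the
#' optimistic per-item step. TPR/FPR are cumulative sums over thresholds,
#' and AUC is the trapezoid over (FPR, TPR) including the (0,0) and (1,1)
#' endpoints — equal to the tie-corrected Mann-Whitney statistic.
#'
#' @param scores Numeric score per bin (higher = more positive-like).
#' @param labels Logical (or 0/1) positive-class indicator per bin.
#' @return Object of class `roc_result`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative bin")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))            # tie blocks in descending order
  tp <- cumsum(tapply(l, grp, sum))
  fp <- cumsum(tapply(!l, grp, sum))
  tpr <- c(0, unname(tp) / n_pos)
  fpr <- c(0, unname(fp) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = unique(s), fpr = fpr, tpr = tpr, auc = auc,
                 n_positive = n_pos, n_negative = n_neg),
            class = "roc_result")
}

#' Combine two mark tracks into one predictor
#'
#' Element-wise arithmetic mean of two per-bin score tracks on comparable
#' normalized scales — the combined-histone-code predictor.
#'
#' @param a,b Numeric per-bin tracks. If named, names must agree.
#' @param method Only `"mean"` is implemented.
#' @return Combined score track.
#' @export
combine_marks <- function(a, b, method = "mean") {
  method <- match.arg(method, "mean")
  if (length(a) != length(b)) stop("mismatched bin sets")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("mismatched bin sets (names differ)")
  (a + b) / 2
}

#' Consensus peaks across replicates
#'
#' All replicate peaks are union-merged; a merged interval is retained iff
#' at least `min_support` replicates contribute at least one overlapping
#' original peak. With a single replicate all peaks are retained.
#'
#' @param peak_sets List of peak tables (chrom, start, end), one per
#'   replicate.
#' @param min_support Minimum number of supporting replicates (default 2).
#' @return data.table of merged peaks with a `support` column.
#' @export
consensus_peaks <- function(peak_sets, min_support = 2L) {
  if (length(peak_sets) == 0L) stop("need at least one replicate")
  if (length(peak_sets) == 1L) {
    out <- data.table::as.data.table(peak_sets[[1]])[, c("chrom", "start", "end")]
    out$support <- 1L
    return(out[])
  }
  all_peaks <- data.table::rbindlist(lapply(seq_along(peak_sets), function(i) {
    p <- data.table::as.data.table(peak_sets[[i]])
    data.table::data.table(chrom = p$chrom, start = p$start, end = p$end,
                           replicate = i)
  }))
  gr <- .as_granges(all_peaks)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  support <- tapply(all_peaks$replicate[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits),
                    function(r) length(unique(r)))
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    support = as.integer(support[as.character(seq_along(merged))])
  )
  out[out$support >= min_support, ][]
}

#' Peak presence per bin
#'
#' TRUE iff the bin overlaps any peak by at least 1 bp (half-open
#' coordinates: a peak ending exactly at the bin start does not overlap).
#'
#' @param bins Bin table.
#' @param peaks Peak table (chrom, start, end).
#' @return Logical vector named by bin_id.
#' @export
bin_presence <- function(bins, peaks) {
  bins <- data.table::as.data.table(bins)
  out <- stats::setNames(rep(FALSE, nrow(bins)), bins$bin_id)
  if (nrow(peaks) == 0L) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(bins), .as_granges(peaks)))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Odds-ratio enrichment between two presence calls
#'
#' Builds the 2x2 table (a = both, b = A only, c = B only, d = neither)
#' over the bin universe, reports the sample odds ratio `ad/bc` (Haldane
#' 0.5 correction on all cells when any cell is zero — note this differs
#' from the conditional-MLE estimate printed by `stats::fisher.test`), and
#' a two-sided Fisher exact p-value computed by summing hypergeometric
#' point probabilities no larger than the observed table's.
#'
#' @param presence_a,presence_b Logical vectors over the same universe.
#' @return Object of class `overlap_table`: list with `a`,`b`,`c`,`d`,
#'   `odds_ratio`, `p_value`, `haldane`.
#' @export
overlap_enrichment <- function(presence_a, presence_b) {
  stopifnot(length(presence_a) == length(presence_b))
  if (length(presence_a) == 0L) stop("empty bin universe")
  presence_a <- as.logical(presence_a)
  presence_b <- as.logical(presence_b)
  a <- sum(presence_a & presence_b)
  b <- sum(presence_a & !presence_b)
  c_ <- sum(!presence_a & presence_b)
  d <- sum(!presence_a & !presence_b)
  haldane <- any(c(a, b, c_, d) == 0L)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  structure(list(a = a, b = b, c = c_, d = d, odds_ratio = or,
                 p_value = fisher_exact_p(a, b, c_, d), haldane = haldane),
            class = "overlap_table")
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose point probability does not exceed the observed one (up to a
#' 1 + 1e-7 relative tolerance for floating-point ties, the standard
#' convention).
#'
#' @param a,b,c,d Cell counts: a both, b A-only, c B-only, d neither.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # size of A
  k <- a + c          # size of B
  n_tot <- a + b + c + d
  lo <- max(0L, k - (n_tot - m))
  hi <- min(m, k)
  x <- lo:hi
  logp <- stats::dhyper(x, m, n_tot - m, k, log = TRUE)
  obs <- stats::dhyper(a, m, n_tot - m, k, log = TRUE)
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Stratified odds ratios over mark-state strata
#'
#' For each stratum of an A-defined categorisation (e.g. H3K9me3-only /
#' H3K27me3-only / both / neither), computes one 2x2 of binding vs
#' membership in that stratum against all other bins.
#'
#' @param binding Logical presence vector (e.g. protein binding).
#' @param strata Factor/character vector of stratum labels per bin.
#' @return Named list of `overlap_table`s, one per stratum level.
#' @export
stratified_enrichment <- function(binding, strata) {
  stopifnot(length(binding) == length(strata))
  lv <- if (is.factor(strata)) levels(strata)
        else sort(unique(strata), method = "radix")  # locale-independent
  out <- lapply(lv, function(s) overlap_enrichment(binding, strata == s))
  stats::setNames(out, lv)
}

#' Venn region counts for k presence vectors
#'
#' @param presence Named list (k <= 4) of logical vectors over the same
#'   universe.
#' @return Named integer vector over the 2^k regions; names like
#'   `"A&!B"`; counts sum to the universe size.
#' @export
venn_partition <- function(presence) {
  k <- length(presence)
  if (k < 1L || k > 4L) stop("between 1 and 4 sets supported")
  n <- unique(vapply(presence, length, 1L))
  if (length(n) != 1L) stop("presence vectors differ in length")
  if (is.null(names(presence))) names(presence) <- LETTERS[seq_len(k)]
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(combos) <- names(presence)
  counts <- apply(combos, 1, function(row) {
    sel <- rep(TRUE, n)
    for (j in seq_len(k))
      sel <- sel & (if (row[j]) presence[[j]] else !presence[[j]])
    sum(sel)
  })
  lab <- apply(combos, 1, function(row)
    paste(ifelse(row, names(presence), paste0("!", names(presence))),
          collapse = "&"))
  stats::setNames(as.integer(counts), lab)
}

#' Group bins by signal level with equidistant rank breakpoints
#'
#' Group 1 holds all zero-level bins. The remaining bins are sorted by
#' level and `n_breakpoints` equidistant breakpoints (including the lowest
#' and highest level) are extracted at ranks
#' `round(i * (m - 1) / (n_breakpoints - 1)) + 1`. Each pair of
#' consecutive non-identical breakpoint values defines a half-open level
#' interval (the last interval is closed at the top), so heavily tied data
#' yield fewer, never empty, groups.
#'
#' @param levels Non-negative per-bin levels.
#' @param n_breakpoints Number of breakpoints (default 15), giving at most
#'   `n_breakpoints - 1` interval groups on top of the zero group.
#' @return Object of class `group_assignment`: list with `group` (integer
#'   per bin; 1 = zero group), `breaks` (data.frame lower/upper per
#'   interval group) and `sizes`.
#' @export
group_by_level <- function(levels, n_breakpoints = 15L) {
  if (any(levels < 0)) stop("levels must be non-negative")
  group <- integer(length(levels))
  group[levels == 0] <- 1L
  nz <- which(levels > 0)
  if (length(nz) == 0L) {
    warning("no nonzero levels; single group returned")
    return(structure(list(group = pmax(group, 1L),
                          breaks = data.frame(lower = numeric(0),
                                              upper = numeric(0)),
                          sizes = stats::setNames(length(levels), "zero")),
                     class = "group_assignment"))
  }
  v <- sort(levels[nz])
  m <- length(v)
  ranks <- round((seq_len(n_breakpoints) - 1) * (m - 1) / (n_breakpoints - 1)) + 1
  bp <- unique(v[ranks])
  if (length(bp) == 1L) bp <- c(bp, bp)  # all nonzero levels identical
  lower <- utils::head(bp, -1)
  upper <- utils::tail(bp, -1)
  ng <- length(lower)
  for (j in seq_len(ng)) {
    inside <- if (j == ng) levels[nz] >= lower[j] & levels[nz] <= upper[j]
              else levels[nz] >= lower[j] & levels[nz] < upper[j]
    group[nz[inside]] <- j + 1L
  }
  sizes <- tabulate(group, nbins = ng + 1L)
  structure(list(group = group,
                 breaks = data.frame(lower = lower, upper = upper),
                 sizes = stats::setNames(sizes,
                                         c("zero", sprintf("g%d", seq_len(ng))))),
            class = "group_assignment")
}
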