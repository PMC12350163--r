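#' Count fragments per bin with a minimum-overlap rule
#'
#' A fragment contributes to every bin covering at least
#' `min_overlap_fraction` of the fragment's length (ties included, so a
#' 100 bp fragment split 50/50 across a bin boundary is counted in both
#' bins). Fragments on sequences absent from the bin table are skipped and
#' tallied in the `"skipped"` attribute.
#'
#' @param bins Bin table (chrom, start, end, bin_id; 0-based half-open).
#' @param fragments data.table of fragments (chrom, start, end, strand).
#' @param min_overlap_fraction Required overlap as a fraction of fragment
#'   length, in (0, 1] (default 0.5).
#' @param strand `"+"`, `"-"` or `"both"`: strand filter applied to the
#'   fragments before counting.
#' @return Integer vector of counts, one per bin, named by bin_id, with
#'   attribute `skipped` (fragments on unknown sequences).
#' @export
count_fragments <- function(bins, fragments, min_overlap_fraction = 0.5,
                            strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  bins <- data.table::as.data.table(bins)
  fragments <- data.table::as.data.table(fragments)
  if (strand != "both") {
    keep_strand <- fragments[["strand"]] == strand
    fragments <- fragments[keep_strand, ]
  }

  counts <- stats::setNames(integer(nrow(bins)), bins$bin_id)
  known <- fragments$chrom %in% unique(bins$chrom)
  skipped <- sum(!known)
  fragments <- fragments[known, ]
  if (nrow(fragments) > 0L) {
    fr_gr <- .as_granges(fragments)
    bin_gr <- .as_granges(bins)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(fr_gr, bin_gr))
    if (length(hits) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(fr_gr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(bin_gr)[S4Vectors::subjectHits(hits)]))
      frlen <- fragments$end - fragments$start
      keep <- ov >= min_overlap_fraction * frlen[S4Vectors::queryHits(hits)]
      tab <- tabulate(S4Vectors::subjectHits(hits)[keep], nbins = nrow(bins))
      counts[] <- as.integer(tab)
    }
  }
  attr(counts, "skipped") <- skipped
  counts
}

#' Mappability-corrected FPKM
#'
#' Fragments per kilobase of *mappable* bin length per million mapped
#' reads: `count * 1e9 / (library_size * bin_length * mappability)`.
#'
#' @param counts Integer counts per bin.
#' @param bin_lengths Bin lengths in bp.
#' @param mappability Mappable fraction per bin (must be > 0; upstream
#'   filtering at >= 0.2 guarantees this).
#' @param library_size Total mapped reads in the library.
#' @return Numeric normalized values.
#' @export
normalize_fpkm <- function(counts, bin_lengths, mappability, library_size) {
  if (library_size <= 0) stop("library size must be positive")
  if (any(mappability <= 0)) stop("mappability must be positive for FPKM")
  counts * 1e9 / (library_size * bin_lengths * mappability)
}

#' Counts per million mapped reads
#'
#' @param counts Integer counts per bin.
#' @param library_size Total mapped reads.
#' @return Numeric cpm values.
#' @export
normalize_cpm <- function(counts, library_size) {
  if (library_size <= 0) stop("library size must be positive")
  counts * 1e6 / library_size
}

#' Coverage-style fragment counts per window
#'
#' Number of fragments overlapping each window by at least 1 bp — the
#' quantification used on fine window grids (e.g. the 50 bp
#' background-subtraction grid), where a minimum-overlap-fraction rule
#' would be meaningless for fragments longer than the window.
#'
#' @param windows Window table (chrom, start, end; 0-based half-open).
#' @param fragments data.table of fragments.
#' @return Numeric vector of counts per window.
#' @export
window_coverage <- function(windows, fragments) {
  fragments <- data.table::as.data.table(fragments)
  known <- fragments$chrom %in% unique(windows$chrom)
  fragments <- fragments[known, ]
  if (nrow(fragments) == 0L) return(numeric(nrow(windows)))
  suppressWarnings(as.numeric(GenomicRanges::countOverlaps(
    .as_granges(windows), .as_granges(fragments))))
}

#' SES-style background scale factor
#'
#' Signal-extraction scaling: the scale is estimated from the portion of
#' the genome where enrichment is absent. Windows are ordered by signal
#' (ties broken by index) and the lowest `lowest_fraction` defines
#' `s = sum(signal) / sum(background)` over that subset, clamped to
#' [1e-3, 1e3]. An all-zero background yields `s = 1` with a warning.
#'
#' @param signal,background Numeric per-window values on the same grid.
#' @param lowest_fraction Fraction of windows (by lowest signal) used
#'   (default 0.5).
#' @return Scalar scale factor.
#' @export
ses_scale_factor <- function(signal, background, lowest_fraction = 0.5) {
  stopifnot(length(signal) == length(background))
  if (all(background == 0)) {
    warning("all-zero background; scale factor set to 1")
    return(1)
  }
  n_low <- max(1L, floor(lowest_fraction * length(signal)))
  ord <- order(signal, seq_along(signal))[seq_len(n_low)]
  denom <- sum(background[ord])
  if (denom == 0) {
    warning("zero background over the low-signal subset; scale factor set to 1")
    return(1)
  }
  min(max(sum(signal[ord]) / denom, 1e-3), 1e3)
}

#' Background subtraction on a window grid
#'
#' Background is scaled by an SES-style factor, subtracted window-wise, and
#' negative values are clamped to zero.
#'
#' @param signal,background Numeric per-window values on the same grid.
#' @param pseudocount Added to both tracks before subtraction (default 0).
#' @param scale_factor Background scale; `NULL` (default) estimates it with
#'   [ses_scale_factor()].
#' @param lowest_fraction Passed to [ses_scale_factor()].
#' @return Numeric enrichment per window (>= 0), with attribute
#'   `scale_factor`.
#' @export
subtract_background <- function(signal, background, pseudocount = 0,
                                scale_factor = NULL, lowest_fraction = 0.5) {
  stopifnot(length(signal) == length(background))
  if (is.null(scale_factor))
    scale_factor <- ses_scale_factor(signal, background, lowest_fraction)
  out <- pmax((signal + pseudocount) - scale_factor * (background + pseudocount),
              0)
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Aggregate window values into bins
#'
#' Per-bin value is the arithmetic mean over the windows lying fully inside
#' the bin. Bins containing no full window get `NA`.
#'
#' @param bins Bin table.
#' @param windows Window table (chrom, start, end), same coordinate
#'   convention.
#' @param values Numeric per-window values.
#' @return Numeric per-bin means, named by bin_id.
#' @export
aggregate_windows <- function(bins, windows, values) {
  stopifnot(length(values) == nrow(windows))
  bin_gr <- .as_granges(bins)
  win_gr <- .as_granges(windows)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(win_gr, bin_gr, type = "within"))
  out <- stats::setNames(rep(NA_real_, nrow(bins)), bins$bin_id)
  if (length(hits) > 0L) {
    m <- tapply(values[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

#' Median-of-ratios size factors
#'
#' Reference per row is the geometric mean across samples (rows with any
#' zero excluded); the factor for a sample is the median across rows of
#' count/reference.
#'
#' @param counts Numeric matrix, bins x samples.
#' @return Numeric size factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) stop("no row with all-positive counts")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  apply(lc, 2, function(x) exp(stats::median(x - ref)))
}

#' log2 fold change with pseudocount
#'
#' @param mean_treated,mean_control Non-negative mean signal values.
#' @param pseudocount Added to both before the ratio (default 0.01, on the
#'   normalized-signal scale).
#' @return log2((treated + pc) / (control + pc)).
#' @export
log2_fold_change <- function(mean_treated, mean_control, pseudocount = 0.01) {
  if (any(mean_treated < 0) || any(mean_control < 0))
    stop("means must be non-negative")
  log2((mean_treated + pseudocount) / (mean_control + pseudocount))
}

#' Cap-and-log10 transform
#'
#' `log10(min(value, cap) + pseudocount)`, the display transform used for
#' bin-level scatter and violin summaries.
#'
#' @param values Non-negative values.
#' @param cap Upper cap before the log (300 for 1 kb bins, 200 for 10 kb).
#' @param pseudocount Default 1.
#' @return Transformed values.
#' @export
cap_log10 <- function(values, cap = 300, pseudocount = 1) {
  if (any(values < 0)) stop("values must be non-negative")
  log10(pmin(values, cap) + pseudocount)
}

#' Minimum-of-strands statistic
#'
#' Element-wise minimum of forward- and reverse-strand signal; suppresses
#' unistrand signatures so dual-strand piRNA production stands out.
#'
#' @param forward,reverse Numeric per-bin values on the same bin set.
#' @return Element-wise minimum.
#' @export
min_strand <- function(forward, reverse) {
  stopifnot(length(forward) == length(reverse))
  pmin(forward, reverse)
}
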