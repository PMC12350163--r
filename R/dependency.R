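#' Mean knockdown fold-loss per bin across depletion strategies
#'
#' For each strategy, replicate values (cpm or other normalized signal) are
#' averaged within the control and depleted arms, then
#' `fold = (control + pc) / (depleted + pc)`. The per-bin result is the
#' mean of these ratios across strategies (mean of ratios; a
#' ratio-of-means mode is available for sensitivity analyses).
#'
#' @param experiments Named list, one element per depletion strategy, each
#'   a list with `control` and `depleted` numeric matrices (bins x
#'   replicates) on the same bin set.
#' @param pseudocount Added to the rep-averaged values before the ratio.
#' @param mode `"mean_of_ratios"` (default) or `"ratio_of_means"` (single
#'   ratio on strategy-averaged means).
#' @return Numeric mean fold-loss per bin.
#' @export
fold_loss <- function(experiments, pseudocount,
                      mode = c("mean_of_ratios", "ratio_of_means")) {
  mode <- match.arg(mode)
  if (length(experiments) == 0L) stop("need at least one strategy")
  nb <- unique(vapply(experiments, function(e) nrow(as.matrix(e$control)), 1L))
  if (length(nb) != 1L) stop("bin sets differ across strategies")
  ctl <- vapply(experiments, function(e) rowMeans(as.matrix(e$control)),
                numeric(nb))
  dep <- vapply(experiments, function(e) rowMeans(as.matrix(e$depleted)),
                numeric(nb))
  ctl <- matrix(ctl, nrow = nb)
  dep <- matrix(dep, nrow = nb)
  if (mode == "mean_of_ratios")
    rowMeans((ctl + pseudocount) / (dep + pseudocount))
  else
    (rowMeans(ctl) + pseudocount) / (rowMeans(dep) + pseudocount)
}

#' Depth-scaled pseudocount (half a read in cpm units)
#'
#' @param library_size Total mapped reads.
#' @param prior_count Reads added (default 0.5).
#' @return Pseudocount on the cpm scale.
#' @export
cpm_pseudocount <- function(library_size, prior_count = 0.5) {
  prior_count * 1e6 / library_size
}

#' Call Rhino-dependent bins from piRNA knockdown experiments
#'
#' A bin is Rhi-dependent iff its mean piRNA fold-loss across the provided
#' depletion strategies exceeds `threshold_fold` (strictly).
#'
#' @param experiments As in [fold_loss()]: strategy -> (control, depleted)
#'   normalized per-bin piRNA values.
#' @param threshold_fold Fold-loss threshold (default 2).
#' @param pseudocount Pseudocount on the normalized scale.
#' @param mode Passed to [fold_loss()].
#' @return Logical per-bin vector with attribute `fold` (the mean
#'   fold-loss used).
#' @export
classify_rhi_dependent <- function(experiments, threshold_fold = 2,
                                   pseudocount = 0,
                                   mode = "mean_of_ratios") {
  fold <- fold_loss(experiments, pseudocount, mode)
  dep <- fold > threshold_fold
  attr(dep, "fold") <- fold
  dep
}

#' Categorize Rhi-dependent bins by E(z)/Kipferl requirement
#'
#' Within the Rhi-dependent set, a bin is E(z) dependent, Kipf dependent or
#' dependent on both when the corresponding mean fold-loss reaches
#' `threshold_fold`; bins reaching it in neither perturbation are
#' `"neither"`.
#'
#' @param rhi_dependent Logical per-bin Rhi dependency calls.
#' @param fold_ez,fold_kipf Mean fold-loss per bin under E(z) / Kipf
#'   depletion (from [fold_loss()]), same bin set.
#' @param threshold_fold Fold-loss threshold (default 4).
#' @return data.table per Rhi-dependent bin: bin (index), fold_ez,
#'   fold_kipf, category in {Ez_dep, Kipf_dep, both, neither}; thresholds
#'   recorded in attributes.
#' @export
classify_ez_kipf <- function(rhi_dependent, fold_ez, fold_kipf,
                             threshold_fold = 4) {
  stopifnot(length(rhi_dependent) == length(fold_ez),
            length(fold_ez) == length(fold_kipf))
  idx <- which(rhi_dependent)
  ez <- fold_ez[idx] >= threshold_fold
  kf <- fold_kipf[idx] >= threshold_fold
  category <- ifelse(ez & kf, "both",
                     ifelse(ez, "Ez_dep", ifelse(kf, "Kipf_dep", "neither")))
  out <- data.table::data.table(bin = idx, fold_ez = fold_ez[idx],
                                fold_kipf = fold_kipf[idx],
                                category = category)
  data.table::setattr(out, "threshold_fold", threshold_fold)
  out[]
}

#' Kipferl dependency of high-confidence Rhi peaks
#'
#' Control-replicate peaks with fold enrichment >= `min_fold` are
#' union-merged into a high-confidence set. Peaks on unplaced contigs or
#' overlapping (>= 1 bp) any peak present in rhi knockdown are excluded.
#' Remaining peaks are Kipf-independent iff they overlap a Rhi peak called
#' in Kipf knockdown, else Kipf-dependent.
#'
#' @param control_peak_sets List (one per control replicate) of peak tables
#'   with a `fold_enrichment` column.
#' @param rhikd_peaks,kipfkd_peaks Peak tables from rhi / kipf knockdown
#'   (may have zero rows).
#' @param min_fold Minimum fold enrichment (default 3).
#' @param unplaced_pattern Regex identifying unplaced contigs by sequence
#'   name (default: names containing "Scaffold"/"rand" or lacking a "chr"
#'   prefix).
#' @return data.table of high-confidence peaks with columns chrom, start,
#'   end, excluded, reason (unplaced_contig / present_in_rhiKD / ""),
#'   kipf_class (dependent / independent / NA for excluded peaks).
#' @export
classify_peaks_kipf <- function(control_peak_sets, rhikd_peaks, kipfkd_peaks,
                                min_fold = 3,
                                unplaced_pattern = "Scaffold|rand|^(?!chr)") {
  filtered <- lapply(control_peak_sets, function(p) {
    p <- data.table::as.data.table(p)
    if (!"fold_enrichment" %in% names(p))
      stop("control peaks need a fold_enrichment column")
    p[p$fold_enrichment >= min_fold, c("chrom", "start", "end")]
  })
  all_peaks <- data.table::rbindlist(filtered)
  if (nrow(all_peaks) == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), excluded = logical(0),
                                  reason = character(0),
                                  kipf_class = character(0)))
  merged <- GenomicRanges::reduce(.as_granges(all_peaks))
  hc <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged))

  unplaced <- grepl(unplaced_pattern, hc$chrom, perl = TRUE)
  in_rhikd <- .overlaps_any(hc, rhikd_peaks) & !unplaced
  hc$excluded <- unplaced | in_rhikd
  hc$reason <- ifelse(unplaced, "unplaced_contig",
                      ifelse(in_rhikd, "present_in_rhiKD", ""))
  in_kipfkd <- .overlaps_any(hc, kipfkd_peaks)
  hc$kipf_class <- ifelse(hc$excluded, NA_character_,
                          ifelse(in_kipfkd, "independent", "dependent"))
  hc[]
}

.overlaps_any <- function(query, subject) {
  subject <- data.table::as.data.table(subject)
  if (is.null(subject) || nrow(subject) == 0L)
    return(rep(FALSE, nrow(query)))
  suppressWarnings(IRanges::overlapsAny(.as_granges(query),
                                        .as_granges(subject)))
}

#' Rank bins by signal change and summarize responder tracks per group
#'
#' Bins are ranked by the primary change (delta, ascending: strongest loss
#' first) and partitioned into `n_groups` equal-size groups, remainder bins
#' going to the lowest-rank groups; ties are broken deterministically by
#' bin id. Optionally the analysis is restricted to bins whose secondary
#' mark signal exceeds the given percentile of euchromatic bins.
#'
#' @param delta Named numeric per-bin change (condition - control).
#' @param responders Named list of numeric per-bin responder changes.
#' @param n_groups Number of equal-size groups (default 6).
#' @param secondary Optional numeric per-bin secondary-mark signal used for
#'   the restriction.
#' @param compartment Per-bin compartment labels (required when `secondary`
#'   is given).
#' @param percentile Euchromatic percentile (default 90) of `secondary`
#'   above which bins are kept.
#' @return list with `bins` (names of analysed bins), `group` (integer per
#'   analysed bin), `summary` (data.frame group x responder mean delta) and
#'   `threshold` (restriction cutoff, or NA).
#' @export
delta_group_analysis <- function(delta, responders, n_groups = 6L,
                                 secondary = NULL, compartment = NULL,
                                 percentile = 90) {
  if (is.null(names(delta))) names(delta) <- as.character(seq_along(delta))
  keep <- rep(TRUE, length(delta))
  threshold <- NA_real_
  if (!is.null(secondary)) {
    if (is.null(compartment))
      stop("restriction requires compartment labels")
    stopifnot(length(secondary) == length(delta),
              length(compartment) == length(delta))
    eu <- secondary[compartment == "euchromatin"]
    if (length(eu) == 0L) stop("no euchromatic bins for the percentile")
    threshold <- stats::quantile(eu, percentile / 100, names = FALSE)
    keep <- secondary > threshold
  }
  d <- delta[keep]
  if (length(d) < n_groups) stop("fewer bins than groups after restriction")
  ord <- order(d, names(d))
  base <- length(d) %/% n_groups
  rem <- length(d) %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  group_sorted <- rep(seq_len(n_groups), times = sizes)
  group <- integer(length(d))
  group[ord] <- group_sorted
  summary <- data.frame(group = seq_len(n_groups),
                        n = as.integer(sizes),
                        mean_delta = as.numeric(tapply(d, group, mean)))
  for (nm in names(responders)) {
    r <- responders[[nm]][keep]
    summary[[paste0("mean_", nm)]] <- as.numeric(tapply(r, group, mean))
  }
  list(bins = names(d), group = group, summary = summary,
       threshold = threshold)
}
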