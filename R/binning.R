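#' Tile a genome into non-overlapping bins
#'
#' Each sequence is tiled left to right with bins of `bin_size` bp; a final
#' shorter bin at the sequence end is retained. Coordinates are 0-based
#' half-open (BED convention); bin ids are `"chrom:start-end"` in that
#' convention.
#'
#' @param seqlens Named numeric vector of sequence lengths (bp), e.g. from
#'   [read_chrom_sizes()], or a `DNAStringSet` whose widths are used.
#' @param bin_size Bin width in bp (default 1000).
#' @return data.table with columns chrom, start, end, bin_id, sorted by
#'   (chrom in input order, start).
#' @export
tile_genome <- function(seqlens, bin_size = 1000L) {
  seqlens <- .as_seqlens(seqlens)
  if (length(seqlens) == 0L) stop("empty assembly")
  if (bin_size <= 0) stop("bin_size must be positive")
  pieces <- lapply(names(seqlens), function(chrom) {
    len <- seqlens[[chrom]]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.table::data.table(chrom = chrom, start = starts,
                           end = pmin(starts + bin_size, len))
  })
  bins <- data.table::rbindlist(pieces)
  bins$chrom <- factor(bins$chrom, levels = names(seqlens))
  bins <- bins[order(bins$chrom, bins$start), ]
  bins$chrom <- as.character(bins$chrom)
  bins$bin_id <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  bins[]
}

#' Sliding-window bins
#'
#' Windows of `window` bp starting at multiples of `step`, truncated at the
#' sequence end. Windows shorter than `min_size` are flagged
#' (`below_min_size`) but not removed here: removal is an explicit filtering
#' step, and the raw window count is meaningful on its own.
#'
#' @param seqlens As in [tile_genome()].
#' @param window Window width in bp (default 10000).
#' @param step Step between window starts in bp (default 5000).
#' @param min_size Minimum window width in bp (default 5000); shorter
#'   windows are flagged for removal.
#' @return data.table with chrom, start, end, bin_id, below_min_size.
#' @export
slide_genome <- function(seqlens, window = 10000L, step = 5000L,
                         min_size = 5000L) {
  seqlens <- .as_seqlens(seqlens)
  if (length(seqlens) == 0L) stop("empty assembly")
  if (step <= 0 || step > window) stop("need 0 < step <= window")
  pieces <- lapply(names(seqlens), function(chrom) {
    len <- seqlens[[chrom]]
    starts <- seq.int(0L, len - 1L, by = step)
    data.table::data.table(chrom = chrom, start = starts,
                           end = pmin(starts + window, len))
  })
  bins <- data.table::rbindlist(pieces)
  bins$bin_id <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  bins$below_min_size <- (bins$end - bins$start) < min_size
  bins[]
}

#' Genome-wide k-mer mappability
#'
#' Emulates unique short-read alignability with exact k-mer matching: an
#' n-mer is unique iff its sequence occurs exactly once in the genome when
#' both strands are considered (a palindromic n-mer, equal to its own
#' reverse complement, counts its two strand orientations as one placement).
#' Any n-mer containing a non-ACGT symbol is treated as non-unique.
#'
#' Per-position mappability is the number of unique n-mers overlapping the
#' position divided by `n` (denominator `n` also near sequence ends, where
#' fewer than `n` n-mers overlap, so ends are slightly penalized). Per-bin
#' mappability is the number of unique n-mer start positions inside the bin
#' divided by the bin length.
#'
#' @param genome `DNAStringSet` of genome sequences.
#' @param n Read length in bp (>= 2); 100 for typical chromatin fragments,
#'   26 for small-RNA reads.
#' @return Object of class `mappability_track`: list with `n`,
#'   `unique_start` (per sequence, logical per n-mer start) and
#'   `per_position` (per sequence, numeric in [0,1]).
#' @export
compute_mappability <- function(genome, n = 100L) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must have unique names")
  if (n < 2) stop("n must be >= 2")
  n <- as.integer(n)
  lens <- Biostrings::width(genome)

  too_short <- lens < n
  if (any(too_short))
    warning("sequence(s) shorter than n get mappability 0: ",
            paste(names(genome)[too_short], collapse = ", "))

  fwd <- lapply(seq_along(genome), function(i) {
    if (too_short[i]) return(character(0))
    s <- as.character(genome[[i]])
    substring(s, 1:(lens[i] - n + 1L), n:lens[i])
  })
  # n-mer at forward position j reverse-complements to the j-th element of
  # the reversed k-mer list of the reverse-complemented sequence
  rev_ <- lapply(seq_along(genome), function(i) {
    if (too_short[i]) return(character(0))
    s <- as.character(Biostrings::reverseComplement(genome[[i]]))
    rev(substring(s, 1:(lens[i] - n + 1L), n:lens[i]))
  })
  kf <- unlist(fwd, use.names = FALSE)
  kr <- unlist(rev_, use.names = FALSE)
  canon <- pmin(kf, kr)
  cnt <- data.table::data.table(k = canon)[, .n_occ := .N, by = "k"]$.n_occ
  ok <- cnt == 1L & !grepl("[^ACGT]", kf)

  idx_end <- cumsum(vapply(fwd, length, 1L))
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  unique_start <- lapply(seq_along(genome), function(i) {
    if (too_short[i]) return(logical(0))
    ok[idx_start[i]:idx_end[i]]
  })
  names(unique_start) <- names(genome)

  per_position <- lapply(seq_along(genome), function(i) {
    L <- lens[i]
    if (too_short[i]) return(numeric(L))
    u <- unique_start[[i]]
    # overlap count at position p = number of unique starts in
    # [p - n + 1, p] intersected with valid start range
    cs <- c(0, cumsum(u))
    p <- seq_len(L)
    hi <- pmin(p, length(u))
    lo <- pmax(p - n + 1L, 1L)
    pmin((cs[hi + 1L] - cs[lo]) / n, 1)
  })
  names(per_position) <- names(genome)

  structure(list(n = n, unique_start = unique_start,
                 per_position = per_position,
                 seqlens = stats::setNames(as.numeric(lens), names(genome))),
            class = "mappability_track")
}

#' Per-bin mappability from a mappability track
#'
#' @param bins Bin table (e.g. [tile_genome()]).
#' @param track `mappability_track` from [compute_mappability()].
#' @return `bins` with a `mappability` column: unique n-mer starts in the
#'   bin divided by bin length.
#' @export
bin_mappability <- function(bins, track) {
  stopifnot(inherits(track, "mappability_track"))
  bins <- data.table::copy(data.table::as.data.table(bins))
  mp <- numeric(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    sel <- which(bins$chrom == chrom)
    u <- track$unique_start[[chrom]]
    if (is.null(u)) stop("no mappability for sequence ", chrom)
    cs <- c(0, cumsum(u))
    lo <- pmin(bins$start[sel], length(u)) # starts are 0-based
    hi <- pmin(bins$end[sel], length(u))
    mp[sel] <- (cs[hi + 1L] - cs[lo + 1L]) / (bins$end[sel] - bins$start[sel])
  }
  bins$mappability <- mp
  bins[]
}

#' Filter bins by mappability, size and excluded sequences
#'
#' Retains bins with mappability >= `min_mappability` (strictly-less bins
#' are removed), length >= `min_size`, and sequence name not excluded
#' (mitochondrial sequences, typically). Removal tallies per criterion are
#' attached as the `"filter_report"` attribute; a bin failing several
#' criteria is tallied under the first one in the order mappability, size,
#' excluded sequence.
#'
#' @param bins Bin table with a `mappability` column (unless
#'   `min_mappability = 0`).
#' @param min_mappability Minimum mappable fraction (default 0.2).
#' @param min_size Minimum bin length in bp (default 0).
#' @param excluded_sequences Character vector of sequence names to drop.
#' @return Filtered bin table with attribute `filter_report`.
#' @export
filter_bins <- function(bins, min_mappability = 0.2, min_size = 0L,
                        excluded_sequences = character(0)) {
  bins <- data.table::as.data.table(bins)
  if (min_mappability > 0 && !"mappability" %in% names(bins))
    stop("bins carry no mappability column")
  low_map <- if (min_mappability > 0) bins$mappability < min_mappability
             else rep(FALSE, nrow(bins))
  small <- (bins$end - bins$start) < min_size & !low_map
  excl <- bins$chrom %in% excluded_sequences & !low_map & !small
  keep <- !(low_map | small | excl)
  out <- bins[keep, ]
  data.table::setattr(out, "filter_report", data.frame(
    criterion = c("low_mappability", "below_min_size", "excluded_sequence",
                  "retained"),
    n = c(sum(low_map), sum(small), sum(excl), sum(keep))
  ))
  out[]
}

#' Assign chromatin compartment labels to bins
#'
#' A bin is labelled iff its midpoint falls inside a labelled interval;
#' otherwise it is labelled `"other"`. Midpoint assignment avoids
#' double-labelling at compartment boundaries.
#'
#' @param bins Bin table.
#' @param compartments data.frame with chrom, start, end (0-based
#'   half-open), label. Intervals must be well-formed and non-overlapping
#'   within a label.
#' @return `bins` with a `compartment` column.
#' @export
assign_compartment <- function(bins, compartments) {
  bins <- data.table::copy(data.table::as.data.table(bins))
  compartments <- data.table::as.data.table(compartments)
  if (any(compartments$start >= compartments$end))
    stop("malformed compartment interval (start >= end)")
  mid <- floor((bins$start + bins$end) / 2)
  mid_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  comp_gr <- .as_granges(compartments)
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(mid_gr, comp_gr, select = "first"))
  bins$compartment <- ifelse(is.na(hit), "other",
                             compartments$label[hit])
  bins[]
}

#' D. melanogaster euchromatin/heterochromatin intervals
#'
#' Pericentromeric heterochromatin and chromosome-arm euchromatin
#' coordinates on the dm6 assembly, as commonly used for ovary chromatin
#' work. The published 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention (chr2R:1-6460000 becomes
#' [0, 6460000)).
#'
#' @return data.frame with chrom, start, end, label.
#' @export
dmel_compartments <- function() {
  eu <- data.frame(
    chrom = c("chr2R", "chr2L", "chr3L", "chr3R", "chrX"),
    start = c(6459999, 0, 0, 4199999, 249999),
    end   = c(25286936, 22160000, 23030000, 32079331, 21500000),
    label = "euchromatin"
  )
  het <- data.frame(
    chrom = c("chr2R", "chr2L", "chr3L", "chr3R"),
    start = c(0, 22159999, 23029999, 0),
    end   = c(6460000, 23513712, 28110227, 4200000),
    label = "heterochromatin"
  )
  rbind(het, eu)
}

.as_seqlens <- function(x) {
  if (methods::is(x, "DNAStringSet"))
    return(stats::setNames(as.numeric(Biostrings::width(x)), names(x)))
  if (is.numeric(x) && (length(x) == 0L || !is.null(names(x)))) return(x)
  stop("expected a named length vector or a DNAStringSet")
}
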