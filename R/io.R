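#' Read a chrom.sizes table
#'
#' Two-column TSV (sequence name, length in bp) as distributed alongside
#' genome assemblies.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of sequence lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1, numeric = 2))
  if (nrow(dt) == 0L) stop("empty chrom.sizes file: ", path)
  if (anyDuplicated(dt$chrom)) stop("duplicated sequence names in ", path)
  if (any(dt$length <= 0)) stop("non-positive sequence length in ", path)
  stats::setNames(as.numeric(dt$length), dt$chrom)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicated sequence names in ", path)
  seqs
}

#' Read aligned fragments from BED6
#'
#' Fragment/read intervals in BED convention (0-based half-open). The strand
#' column is kept; "." is accepted for unstranded data.
#'
#' @param path BED file with at least 6 columns (3 accepted for unstranded).
#' @return data.table with columns chrom, start, end, strand.
#' @export
read_fragments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write fragments to BED6
#'
#' @param frags data.table with chrom, start, end, strand (0-based half-open).
#' @param path Output path.
#' @param name_prefix Feature name prefix for column 4.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path, name_prefix = "frag") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(frags)))
  out <- data.table::data.table(
    chrom = frags$chrom,
    start = as.integer(frags$start),
    end = as.integer(frags$end),
    name = sprintf("%s_%d", name_prefix, seq_len(nrow(frags))),
    score = 0L,
    strand = frags$strand
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peak calls from BED
#'
#' Tolerates 3 to 6+ columns. Columns 7 and 8, when present, are interpreted
#' as fold enrichment over background and q-value (the layout written by
#' common peak callers and by [write_peaks_bed()]); any further columns are
#' preserved as-is.
#'
#' @param path BED file of peaks.
#' @return data.table with chrom, start, end and any of name, score, strand,
#'   fold_enrichment, qvalue present in the file.
#' @export
read_peaks_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("peak BED needs at least 3 columns: ", path)
  cn <- c("chrom", "start", "end", "name", "score", "strand",
          "fold_enrichment", "qvalue")
  data.table::setnames(dt, seq_len(min(ncol(dt), length(cn))),
                       cn[seq_len(min(ncol(dt), length(cn)))])
  dt$chrom <- as.character(dt$chrom)
  if (any(dt$start >= dt$end)) stop("malformed peak interval (start >= end) in ", path)
  dt
}

#' Write peaks to BED6+2 (fold enrichment, q-value)
#'
#' @param peaks data.table with chrom, start, end and optional
#'   fold_enrichment / qvalue columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.table::data.table(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = if ("name" %in% names(peaks)) peaks$name else
      sprintf("peak_%d", seq_len(nrow(peaks))),
    score = 0L,
    strand = ".",
    fold_enrichment = if ("fold_enrichment" %in% names(peaks))
      sprintf("%.4f", peaks$fold_enrichment) else "1.0000",
    qvalue = if ("qvalue" %in% names(peaks))
      sprintf("%.3g", peaks$qvalue) else "0.001"
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genomic bins to BED-like TSV
#'
#' BED4 plus mappability and compartment columns when present.
#'
#' @param bins Bin table from [tile_genome()] and friends.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  out <- data.table::data.table(chrom = bins$chrom,
                                start = as.integer(bins$start),
                                end = as.integer(bins$end),
                                name = bins$bin_id)
  if ("mappability" %in% names(bins))
    out$mappability <- sprintf("%.6f", bins$mappability)
  if ("compartment" %in% names(bins)) out$compartment <- bins$compartment
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: bins / interval data.frames (0-based half-open) -> GRanges.
.as_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand
  )
}
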