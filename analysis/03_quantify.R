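#!/usr/bin/env Rscript

# Stage 3: signal quantification.
#
# Counts mark fragments on a 50 bp window grid (coverage-style), subtracts
# the SES-scaled IgG background, clamps negatives and averages windows per
# retained bin; counts piRNA reads per bin and strand with the >= 50%
# fragment-overlap rule and converts them to cpm per library. Writes the
# per-bin mark signal and piRNA cpm matrices used by stages 4 and 5.

suppressMessages(library(dualmark))

fx <- "results/fixture"
seqlens <- read_chrom_sizes(file.path(fx, "chrom.sizes"))
retained <- read_peaks_bed("results/binning/retained_bins.bed")
names(retained)[4] <- "bin_id"
retained$mappability <- as.numeric(retained$score)
names(retained)[6] <- "compartment"
windows <- tile_genome(seqlens, 50L)

igg <- rowMeans(vapply(sprintf("%s/IgG_rep%d.bed", fx, 1:2), function(f)
  window_coverage(windows, read_fragments_bed(f)), numeric(nrow(windows))))

mark_signal <- lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"),
                      function(mk) {
  per_rep <- lapply(sprintf("%s/%s_rep%d.bed", fx, mk, 1:2), function(f) {
    enr <- subtract_background(
      window_coverage(windows, read_fragments_bed(f)), igg)
    aggregate_windows(retained, windows, enr)
  })
  rowMeans(do.call(cbind, per_rep))
})
cat("Mark signal quantified; mean enrichment H3K9me3 =",
    round(mean(mark_signal$H3K9me3), 2), ", H3K27me3 =",
    round(mean(mark_signal$H3K27me3), 2), "\n")

pirna_files <- sort(grep("^pirna_", list.files(fx), value = TRUE),
                    method = "radix")
pirna <- lapply(pirna_files, function(f) {
  fr <- read_fragments_bed(file.path(fx, f))
  plus <- count_fragments(retained, fr, 0.5, "+")
  minus <- count_fragments(retained, fr, 0.5, "-")
  c(list(file = f, library_size = nrow(fr)),
    list(cpm = normalize_cpm(as.integer(plus) + as.integer(minus), nrow(fr)),
         plus = as.integer(plus), minus = as.integer(minus)))
})
cat("Quantified", length(pirna), "piRNA libraries; median library size",
    stats::median(vapply(pirna, `[[`, 0, "library_size")), "\n")

dir.create("results/quantify", showWarnings = FALSE, recursive = TRUE)
sig <- data.frame(bin_id = retained$bin_id,
                  compartment = retained$compartment,
                  H3K9me3 = mark_signal$H3K9me3,
                  H3K27me3 = mark_signal$H3K27me3)
write.table(sig, "results/quantify/mark_signal.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cpm <- data.frame(bin_id = retained$bin_id,
                  vapply(pirna, `[[`, numeric(nrow(retained)), "cpm"))
names(cpm)[-1] <- sub("\\.bed$", "", vapply(pirna, `[[`, "", "file"))
write.table(cpm, "results/quantify/pirna_cpm.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
stems <- sub("\\.bed$", "", vapply(pirna, `[[`, "", "file"))
plus_m <- vapply(pirna, `[[`, numeric(nrow(retained)), "plus")
minus_m <- vapply(pirna, `[[`, numeric(nrow(retained)), "minus")
colnames(plus_m) <- paste0(stems, ".plus")
colnames(minus_m) <- paste0(stems, ".minus")
strands <- data.frame(bin_id = retained$bin_id, plus_m, minus_m,
                      check.names = FALSE)
write.table(strands, "results/quantify/pirna_strand_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
libs <- data.frame(file = vapply(pirna, `[[`, "", "file"),
                   library_size = vapply(pirna, `[[`, 0, "library_size"))
write.table(libs, "results/quantify/library_sizes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/quantify/{mark_signal,pirna_cpm,pirna_strand_counts,library_sizes}.tsv\n")
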