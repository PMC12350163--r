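#!/usr/bin/env Rscript

# Stage 4: combinatorial-mark classification.
#
# Asks how well each histone mark — and their mean — ranks bins by
# dual-strand piRNA cluster membership (ROC/AUC); calls per-bin peak
# presence from replicate-consensus peaks; quantifies the association of
# Rhino binding with the four mark states as stratified odds ratios with
# Fisher exact p-values; and summarizes mark levels across 15 piRNA-level
# groups built on the minimum-of-strands statistic.

suppressMessages(library(dualmark))

fx <- "results/fixture"
retained <- read_peaks_bed("results/binning/retained_bins.bed")
names(retained)[4] <- "bin_id"
retained$mappability <- as.numeric(retained$score)
sig <- read.delim("results/quantify/mark_signal.tsv")
stopifnot(identical(sig$bin_id, retained$bin_id))

dual <- bin_presence(retained, read_peaks_bed(file.path(fx, "clusters_dual.bed")))
uni <- bin_presence(retained,
                    read_peaks_bed(file.path(fx, "clusters_unistrand.bed")))
combined <- combine_marks(sig$H3K27me3, sig$H3K9me3)
auc <- data.frame(
  target = c("dual_strand", "unistrand"),
  H3K27me3 = c(roc_auc(sig$H3K27me3, dual)$auc, roc_auc(sig$H3K27me3, uni)$auc),
  H3K9me3 = c(roc_auc(sig$H3K9me3, dual)$auc, roc_auc(sig$H3K9me3, uni)$auc),
  combined_mean = c(roc_auc(combined, dual)$auc, roc_auc(combined, uni)$auc))
cat("AUC for predicting cluster bins from mark signal:\n")
print(auc, digits = 3)

presence <- lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"),
                   function(mk) {
  sets <- lapply(sprintf("%s/peaks_%s_rep%d.bed", fx, mk, 1:2), read_peaks_bed)
  bin_presence(retained, consensus_peaks(sets, 2L))
})
rhi_sets <- lapply(sprintf("%s/peaks_rhi_control_rep%d.bed", fx, 1:2),
                   function(f) read_peaks_bed(f)[, c("chrom", "start", "end")])
rhi <- bin_presence(retained, consensus_peaks(rhi_sets, 2L))
strata <- ifelse(presence$H3K9me3 & presence$H3K27me3, "both",
                 ifelse(presence$H3K9me3, "K9only",
                        ifelse(presence$H3K27me3, "K27only", "neither")))
ors <- stratified_enrichment(rhi, strata)
or_df <- do.call(rbind, lapply(names(ors), function(s)
  data.frame(stratum = s, a = ors[[s]]$a, b = ors[[s]]$b, c = ors[[s]]$c,
             d = ors[[s]]$d, odds_ratio = ors[[s]]$odds_ratio,
             p = ors[[s]]$p_value)))
cat("\nRhino binding vs mark state (odds ratios):\n")
print(or_df, digits = 3)
venn <- venn_partition(list(Rhi = rhi, H3K9me3 = presence$H3K9me3,
                            H3K27me3 = presence$H3K27me3))

# 15-group piRNA-level summary on minimum-of-strands FPKM (control libraries)
strands <- read.delim("results/quantify/pirna_strand_counts.tsv",
                      check.names = FALSE)
libs <- read.delim("results/quantify/library_sizes.tsv")
ctl <- grep("_control_", libs$file, value = TRUE)
min_fpkm <- rowMeans(vapply(ctl, function(f) {
  stem <- sub("\\.bed$", "", f)
  lib <- libs$library_size[libs$file == f]
  blen <- retained$end - retained$start
  min_strand(
    normalize_fpkm(strands[[paste0(stem, ".plus")]], blen,
                   retained$mappability, lib),
    normalize_fpkm(strands[[paste0(stem, ".minus")]], blen,
                   retained$mappability, lib))
}, numeric(nrow(retained))))
groups <- group_by_level(min_fpkm, 15L)
summary <- data.frame(
  group = seq_along(groups$sizes), n = as.integer(groups$sizes),
  mean_pirna = as.numeric(tapply(cap_log10(min_fpkm, 300), groups$group, mean)),
  mean_H3K9me3 = as.numeric(tapply(sig$H3K9me3, groups$group, mean)),
  mean_H3K27me3 = as.numeric(tapply(sig$H3K27me3, groups$group, mean)))
cat("\npiRNA-level groups (zero group + level intervals):\n")
print(summary, digits = 3)

dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)
write.table(auc, "results/classify/auc_matrix.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(or_df, "results/classify/or_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(region = names(venn), n = as.integer(venn)),
            "results/classify/venn.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(summary, "results/classify/level_groups.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/classify/{auc_matrix,or_table,venn,level_groups}.tsv\n")
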