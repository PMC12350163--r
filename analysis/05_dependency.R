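#!/usr/bin/env Rscript

# Stage 5: knockdown dependency classification.
#
# Calls Rhino-dependent bins (>2-fold mean piRNA cpm loss across three
# depletion strategies), subdivides them by E(z)/Kipferl requirement
# (>=4-fold mean loss), classifies high-confidence Rhino peaks as
# Kipferl-dependent or -independent, and runs the six-group analysis of
# piRNA change with the 90th-percentile H3K9me3 restriction.

suppressMessages(library(dualmark))

fx <- "results/fixture"
cpm <- read.delim("results/quantify/pirna_cpm.tsv", check.names = FALSE)
libs <- read.delim("results/quantify/library_sizes.tsv")
sig <- read.delim("results/quantify/mark_signal.tsv")
stopifnot(identical(cpm$bin_id, sig$bin_id))
pc <- cpm_pseudocount(stats::median(libs$library_size))

experiments_of <- function(pert) {
  cols <- grep(sprintf("^pirna_%s_", pert), names(cpm), value = TRUE)
  strat <- sub(sprintf("^pirna_%s_(.*)_(control|depleted)_rep\\d+$", pert),
               "\\1", cols)
  lapply(split(cols, strat), function(cc) list(
    control = as.matrix(cpm[, grep("_control_", cc, value = TRUE)]),
    depleted = as.matrix(cpm[, grep("_depleted_", cc, value = TRUE)])))
}

rhi_dep <- classify_rhi_dependent(experiments_of("rhi"), 2, pc)
cat("Rhi-dependent bins (>2-fold mean cpm loss):", sum(rhi_dep), "\n")
dep <- classify_ez_kipf(rhi_dep, fold_loss(experiments_of("ez"), pc),
                        fold_loss(experiments_of("kipf"), pc), 4)
dep$bin_id <- cpm$bin_id[dep$bin]
cat("E(z)/Kipferl categories:\n"); print(table(dep$category))

ctl_peaks <- lapply(sprintf("%s/peaks_rhi_control_rep%d.bed", fx, 1:2),
                    read_peaks_bed)
pd <- classify_peaks_kipf(ctl_peaks,
                          read_peaks_bed(file.path(fx, "peaks_rhi_rhiKD.bed")),
                          read_peaks_bed(file.path(fx, "peaks_rhi_kipfKD.bed")),
                          min_fold = 3)
cat("High-confidence Rhino peaks:", nrow(pd), "->\n")
print(table(ifelse(pd$excluded, pd$reason, pd$kipf_class)))

mean_cpm <- function(pert, arm) {
  cols <- grep(sprintf("^pirna_%s_.*_%s_", pert, arm), names(cpm),
               value = TRUE)
  rowMeans(cpm[, cols])
}
delta_ez <- stats::setNames(mean_cpm("ez", "depleted") -
                              mean_cpm("ez", "control"), cpm$bin_id)
delta_kipf <- mean_cpm("kipf", "depleted") - mean_cpm("kipf", "control")
dg <- delta_group_analysis(delta_ez, list(kipf = delta_kipf), 6L,
                           secondary = sig$H3K9me3,
                           compartment = sig$compartment, percentile = 90)
cat("\nSix groups by piRNA change under E(z) depletion",
    sprintf("(restricted to %d high-H3K9me3 bins):\n", length(dg$bins)))
print(dg$summary, digits = 3)

dir.create("results/dependency", showWarnings = FALSE, recursive = TRUE)
write.table(dep, "results/dependency/dependency_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(pd, "results/dependency/peak_dependency.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dg$summary, "results/dependency/delta_groups.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/dependency/{dependency_table,peak_dependency,delta_groups}.tsv\n")
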