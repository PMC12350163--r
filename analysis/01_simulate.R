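#!/usr/bin/env Rscript

# Stage 1: generate the synthetic cohort.
#
# Builds a toy genome (three 1 Mb chromosomes, a mitochondria-like sequence
# and an unplaced contig, with an exact duplication block for the
# mappability filter), a bin-level truth table (mark states, piRNA cluster
# labels, knockdown dependency classes, Rhino binding, compartments), and
# the full set of sequencing-like inputs: CUT&RUN-style fragment BEDs for
# H3K9me3/H3K27me3 plus an IgG background, stranded piRNA BEDs for every
# knockdown strategy, and peak calls. Everything is written as plain text
# under results/fixture.

suppressMessages(library(dualmark))
suppressMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 42L))))

cfg <- sim_config(seed = opts$seed)
cohort <- simulate_cohort(cfg)
write_fixture(cohort, "results/fixture")

tt <- cohort$truth
cat("Simulated", length(cohort$genome), "sequences,", nrow(tt), "bins\n")
cat("Mark states:\n"); print(table(tt$mark_state))
cat("Cluster labels:\n"); print(table(tt$cluster_label))
cat("Dependency classes (dual-strand bins):\n")
print(table(tt$dependency_class[tt$cluster_label == "dual_strand"]))
cat("Rhino-bound bins:", sum(tt$rhi_bound), "\n")
cat("Fixture written to results/fixture (",
    length(list.files("results/fixture")), "files )\n")
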