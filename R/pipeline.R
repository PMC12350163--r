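#' Analysis configuration
#'
#' All thresholds of the pipeline in one flat structure. Defaults are the
#' standard constants of the analysis: 1 kb bins; 10 kb / 5 kb sliding
#' windows with a 5 kb minimum; 20% minimum mappability; the >= 0.5
#' fragment-overlap rule; a 50 bp background-subtraction grid; fold
#' thresholds 2 (Rhi), 4 (E(z)/Kipf) and 3 (high-confidence peaks);
#' consensus support 2; 15 level breakpoints; 6 delta groups; the 90th
#' percentile restriction; caps 300 (1 kb) / 200 (10 kb) with a log10
#' pseudocount of 1. Unknown keys are rejected.
#'
#' @param ... Overrides for any of the documented keys.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    bin_size = 1000L,
    window = 10000L,
    step = 5000L,
    window_min_size = 5000L,
    mappability_n = 100L,
    min_mappability = 0.2,
    min_overlap_fraction = 0.5,
    subtraction_window = 50L,
    ses_lowest_fraction = 0.5,
    lfc_pseudocount = 0.01,
    cap_1kb = 300,
    cap_10kb = 200,
    cap_log_pseudocount = 1,
    rhi_threshold_fold = 2,
    ez_kipf_threshold_fold = 4,
    peak_min_fold = 3,
    consensus_min_support = 2L,
    n_level_breakpoints = 15L,
    n_delta_groups = 6L,
    secondary_mark_percentile = 90,
    excluded_sequences = c("chrM", "chrM_sim"),
    unplaced_pattern = "Scaffold|rand|^(?!chr)",
    seed = 42L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (cfg$min_overlap_fraction <= 0 || cfg$min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  if (cfg$min_mappability < 0 || cfg$min_mappability > 1)
    stop("min_mappability must be in [0, 1]")
  if (cfg$step <= 0 || cfg$step > cfg$window)
    stop("need 0 < step <= window")
  class(cfg) <- "analysis_config"
  cfg
}

# Locale-independent sort, so run outputs do not depend on LC_COLLATE.
.rsort <- function(x) sort(x, method = "radix")

# Locale-independent tabulation with rows ordered by C collation.
.count_table <- function(x, name) {
  f <- factor(x, levels = .rsort(unique(x)))
  out <- as.data.frame(table(f))
  names(out) <- c(name, "Freq")
  out
}

# List the fixture files the pipeline consumes; fail fast on missing ones.
.fixture_manifest <- function(fixture_dir) {
  need <- c("genome.fa", "chrom.sizes", "compartments.tsv",
            "clusters_dual.bed", "clusters_unistrand.bed",
            "peaks_rhi_rhiKD.bed", "peaks_rhi_kipfKD.bed")
  files <- list.files(fixture_dir)
  missing <- setdiff(need, files)
  if (length(missing))
    stop("missing input file(s) in ", fixture_dir, ": ",
         paste(missing, collapse = ", "))
  list(
    dir = fixture_dir,
    marks = lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"), function(mk)
      .rsort(grep(sprintf("^%s_rep\\d+\\.bed$", mk), files, value = TRUE))),
    igg = .rsort(grep("^IgG_rep\\d+\\.bed$", files, value = TRUE)),
    pirna = .rsort(grep("^pirna_.*\\.bed$", files, value = TRUE)),
    mark_peaks = lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"),
                        function(mk)
      .rsort(grep(sprintf("^peaks_%s_rep\\d+\\.bed$", mk), files,
                  value = TRUE))),
    rhi_control_peaks = .rsort(grep("^peaks_rhi_control_rep\\d+\\.bed$",
                                    files, value = TRUE))
  )
}

# Per-bin background-subtracted mark enrichment, averaged over replicates.
.quantify_mark <- function(bins, windows, frag_files, igg_counts, config,
                           fixture_dir) {
  per_rep <- lapply(frag_files, function(f) {
    frags <- read_fragments_bed(file.path(fixture_dir, f))
    sig <- window_coverage(windows, frags)
    enr <- subtract_background(sig, igg_counts,
                               lowest_fraction = config$ses_lowest_fraction)
    aggregate_windows(bins, windows, enr)
  })
  rowMeans(do.call(cbind, per_rep))
}

# Stranded per-bin cpm for one piRNA library file.
.quantify_pirna <- function(bins, path, config) {
  frags <- read_fragments_bed(path)
  plus <- count_fragments(bins, frags, config$min_overlap_fraction, "+")
  minus <- count_fragments(bins, frags, config$min_overlap_fraction, "-")
  lib <- nrow(frags)
  list(plus = plus, minus = minus, total_cpm = normalize_cpm(plus + minus, lib),
       plus_cpm = normalize_cpm(plus, lib),
       minus_cpm = normalize_cpm(minus, lib), library_size = lib)
}

# Parse pirna_<pert>_<strategy>_<arm>_rep<k>.bed names into a design table.
.pirna_design <- function(pirna_files) {
  m <- regmatches(pirna_files,
                  regexec("^pirna_([a-z]+)_([A-Za-z_]+)_(control|depleted)_rep(\\d+)\\.bed$",
                          pirna_files))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("unrecognized piRNA file name(s): ",
                     paste(pirna_files[bad], collapse = ", "))
  data.table::data.table(
    file = pirna_files,
    perturbation = vapply(m, `[`, "", 2L),
    strategy = vapply(m, `[`, "", 3L),
    arm = vapply(m, `[`, "", 4L),
    replicate = as.integer(vapply(m, `[`, "", 5L)))
}

#' Run the full bin-level analysis on a fixture directory
#'
#' Executes binning (tiling, mappability, filtering, compartments),
#' quantification (windowed counting, SES background subtraction, per-bin
#' piRNA cpm), classification (ROC/AUC per mark and combined, peak
#' presence, stratified odds ratios, Venn counts, level groups),
#' dependency calling (Rhi / E(z)-Kipf bins, Kipf peak classes, the
#' rank-grouped delta analysis) and writes the report tables plus a run
#' manifest to `outdir`.
#'
#' @param fixture_dir Directory with the input files (see
#'   [write_fixture()] for the layout).
#' @param config An [analysis_config()].
#' @param outdir Output directory for the result tables; `NULL` skips
#'   writing.
#' @return list with the bin table, per-bin signal tracks, classification
#'   and dependency results, report tables and the manifest.
#' @export
run_pipeline <- function(fixture_dir, config = analysis_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  manifest_in <- .fixture_manifest(fixture_dir)
  fp <- function(f) file.path(fixture_dir, f)

  ## binning
  genome <- read_genome_fasta(fp("genome.fa"))
  seqlens <- read_chrom_sizes(fp("chrom.sizes"))
  if (!identical(stats::setNames(as.numeric(Biostrings::width(genome)),
                                 names(genome)), seqlens))
    stop("chrom.sizes does not match the FASTA")
  bins <- tile_genome(seqlens, config$bin_size)
  track <- compute_mappability(genome, config$mappability_n)
  bins <- bin_mappability(bins, track)
  compartments <- data.table::fread(fp("compartments.tsv"))
  bins <- assign_compartment(bins, compartments)
  retained <- filter_bins(bins, config$min_mappability,
                          excluded_sequences = config$excluded_sequences)
  filter_report <- attr(retained, "filter_report")

  ## quantification: marks on the subtraction-window grid
  windows <- tile_genome(seqlens, config$subtraction_window)
  igg_counts <- rowMeans(vapply(manifest_in$igg, function(f)
    window_coverage(windows, read_fragments_bed(fp(f))),
    numeric(nrow(windows))))
  mark_signal <- lapply(names(manifest_in$marks), function(mk)
    .quantify_mark(retained, windows, manifest_in$marks[[mk]], igg_counts,
                   config, fixture_dir))
  names(mark_signal) <- names(manifest_in$marks)

  ## quantification: piRNA libraries
  design <- .pirna_design(manifest_in$pirna)
  pirna <- lapply(design$file, function(f) .quantify_pirna(retained, fp(f),
                                                           config))
  names(pirna) <- design$file

  ## classification
  dual_presence <- bin_presence(retained, read_peaks_bed(fp("clusters_dual.bed")))
  uni_presence <- bin_presence(retained,
                               read_peaks_bed(fp("clusters_unistrand.bed")))
  combined <- combine_marks(mark_signal$H3K27me3, mark_signal$H3K9me3)
  predictors <- list(H3K27me3 = mark_signal$H3K27me3,
                     H3K9me3 = mark_signal$H3K9me3,
                     combined_mean = combined)
  targets <- list(dual_strand = dual_presence, unistrand = uni_presence)
  auc_matrix <- do.call(rbind, lapply(names(targets), function(tg) {
    data.frame(target = tg, t(vapply(predictors, function(p)
      roc_auc(p, targets[[tg]])$auc, numeric(1))))
  }))

  mark_presence <- lapply(names(manifest_in$mark_peaks), function(mk) {
    sets <- lapply(manifest_in$mark_peaks[[mk]], function(f)
      read_peaks_bed(fp(f)))
    bin_presence(retained, consensus_peaks(sets, config$consensus_min_support))
  })
  names(mark_presence) <- names(manifest_in$mark_peaks)
  rhi_control_sets <- lapply(manifest_in$rhi_control_peaks, function(f)
    read_peaks_bed(fp(f)))
  rhi_presence <- bin_presence(
    retained, consensus_peaks(lapply(rhi_control_sets, function(p)
      p[, c("chrom", "start", "end")]), config$consensus_min_support))
  strata <- ifelse(mark_presence$H3K9me3 & mark_presence$H3K27me3, "both",
                   ifelse(mark_presence$H3K9me3, "K9only",
                          ifelse(mark_presence$H3K27me3, "K27only", "neither")))
  or_tables <- stratified_enrichment(rhi_presence, strata)
  venn <- venn_partition(list(Rhi = rhi_presence,
                              H3K9me3 = mark_presence$H3K9me3,
                              H3K27me3 = mark_presence$H3K27me3))

  ## piRNA level groups (minimum-of-strands FPKM, cap + log10)
  ctl <- design$arm == "control"
  lib_sizes <- vapply(pirna, function(q) q$library_size, numeric(1))
  fpkm_strand <- function(q, counts)
    normalize_fpkm(counts, retained$end - retained$start,
                   retained$mappability, q$library_size)
  min_fpkm <- rowMeans(vapply(which(ctl), function(i)
    min_strand(fpkm_strand(pirna[[i]], pirna[[i]]$plus),
               fpkm_strand(pirna[[i]], pirna[[i]]$minus)),
    numeric(nrow(retained))))
  level_groups <- group_by_level(min_fpkm, config$n_level_breakpoints)
  level_summary <- data.frame(
    group = seq_along(level_groups$sizes),
    n = as.integer(level_groups$sizes),
    mean_pirna = as.numeric(tapply(cap_log10(min_fpkm, config$cap_1kb,
                                             config$cap_log_pseudocount),
                                   level_groups$group, mean)),
    mean_H3K9me3 = as.numeric(tapply(mark_signal$H3K9me3,
                                     level_groups$group, mean)),
    mean_H3K27me3 = as.numeric(tapply(mark_signal$H3K27me3,
                                      level_groups$group, mean)))

  ## dependency
  pc <- cpm_pseudocount(stats::median(lib_sizes))
  experiments_of <- function(pert) {
    d <- design[design$perturbation == pert, ]
    strat <- factor(d$strategy, levels = .rsort(unique(d$strategy)))
    lapply(split(seq_len(nrow(d)), strat), function(ii) {
      dd <- d[ii, ]
      cpm_mat <- function(arm) {
        sel <- dd$file[dd$arm == arm]
        vapply(sel, function(f) pirna[[f]]$total_cpm, numeric(nrow(retained)))
      }
      list(control = cpm_mat("control"), depleted = cpm_mat("depleted"))
    })
  }
  rhi_dep <- classify_rhi_dependent(experiments_of("rhi"),
                                    config$rhi_threshold_fold, pc)
  fold_ez <- fold_loss(experiments_of("ez"), pc)
  fold_kipf <- fold_loss(experiments_of("kipf"), pc)
  dep_table <- classify_ez_kipf(rhi_dep, fold_ez, fold_kipf,
                                config$ez_kipf_threshold_fold)
  dep_table$bin_id <- retained$bin_id[dep_table$bin]
  dep_counts <- .count_table(dep_table$category, "category")
  origin <- .count_table(retained$compartment[rhi_dep], "compartment")

  peak_dep <- classify_peaks_kipf(rhi_control_sets,
                                  read_peaks_bed(fp("peaks_rhi_rhiKD.bed")),
                                  read_peaks_bed(fp("peaks_rhi_kipfKD.bed")),
                                  config$peak_min_fold,
                                  config$unplaced_pattern)

  ## delta-group analysis: piRNA change under EzKD, Kipf response tracks,
  ## restricted to bins with high H3K9me3 (above the euchromatic percentile)
  mean_cpm <- function(pert, arm) {
    d <- design[design$perturbation == pert & design$arm == arm, ]
    rowMeans(vapply(d$file, function(f) pirna[[f]]$total_cpm,
                    numeric(nrow(retained))))
  }
  delta_ez <- mean_cpm("ez", "depleted") - mean_cpm("ez", "control")
  delta_kipf <- mean_cpm("kipf", "depleted") - mean_cpm("kipf", "control")
  names(delta_ez) <- retained$bin_id
  delta_groups <- delta_group_analysis(
    delta_ez, list(kipf = delta_kipf), config$n_delta_groups,
    secondary = mark_signal$H3K9me3, compartment = retained$compartment,
    percentile = config$secondary_mark_percentile)

  report <- list(auc_matrix = auc_matrix,
                 or_table = .or_table_df(or_tables),
                 venn = data.frame(region = names(venn), n = as.integer(venn)),
                 dependency_counts = dep_counts,
                 dependency_origin = origin,
                 peak_dependency = .count_table(
                   ifelse(peak_dep$excluded, peak_dep$reason,
                          peak_dep$kipf_class), "class"),
                 level_summary = level_summary,
                 delta_summary = delta_groups$summary,
                 filter_report = filter_report)

  result <- list(config = config, bins = bins, retained = retained,
                 mark_signal = mark_signal, pirna_design = design,
                 min_strand_fpkm = min_fpkm,
                 rhi_dependent = rhi_dep, dependency = dep_table,
                 peak_dependency = peak_dep, level_groups = level_groups,
                 delta_groups = delta_groups, auc_matrix = auc_matrix,
                 or_tables = or_tables, venn = venn, report = report)
  if (!is.null(outdir)) result$manifest <- write_report(result, fixture_dir,
                                                        outdir)
  result
}

.or_table_df <- function(or_tables) {
  do.call(rbind, lapply(names(or_tables), function(s) {
    t <- or_tables[[s]]
    data.frame(stratum = s, a = t$a, b = t$b, c = t$c, d = t$d,
               odds_ratio = t$odds_ratio, p_value = t$p_value)
  }))
}

#' Write report tables and a run manifest
#'
#' One TSV per report table, a TSV of per-bin results, and
#' `manifest.tsv` with the config snapshot, input checksums, per-stage row
#' counts, package version and timestamp. Result files other than the
#' manifest are byte-reproducible for identical inputs and config.
#'
#' @param result A [run_pipeline()] result.
#' @param fixture_dir The input directory (for checksums).
#' @param outdir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_report <- function(result, fixture_dir, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    data.table::fwrite(data.table::as.data.table(df),
                       file.path(outdir, paste0(name, ".tsv")), sep = "\t")
  for (nm in names(result$report)) w(result$report[[nm]], nm)
  per_bin <- data.table::data.table(
    bin_id = result$retained$bin_id,
    chrom = result$retained$chrom,
    start = result$retained$start,
    end = result$retained$end,
    mappability = sprintf("%.6f", result$retained$mappability),
    compartment = result$retained$compartment,
    H3K9me3 = sprintf("%.6g", result$mark_signal$H3K9me3),
    H3K27me3 = sprintf("%.6g", result$mark_signal$H3K27me3),
    min_strand_pirna_fpkm = sprintf("%.6g", result$min_strand_fpkm),
    rhi_dependent = result$rhi_dependent)
  w(per_bin, "per_bin")

  cfg <- result$config
  cfg_flat <- vapply(cfg, function(x) paste(format(x), collapse = ","), "")
  inputs <- list.files(fixture_dir, full.names = TRUE)
  sums <- tools::md5sum(inputs[!dir.exists(inputs)])
  manifest <- data.frame(
    key = c(paste0("config.", names(cfg_flat)),
            paste0("md5.", basename(names(sums))),
            "n_bins", "n_retained", "n_rhi_dependent", "n_peaks_highconf",
            "package_version", "timestamp"),
    value = c(unname(cfg_flat), unname(sums),
              nrow(result$bins), nrow(result$retained),
              sum(result$rhi_dependent), nrow(result$peak_dependency),
              as.character(utils::packageVersion("dualmark")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Checksums of the reproducible result files in a report directory
#'
#' All `.tsv` outputs except the manifest (which carries a timestamp).
#'
#' @param outdir A report directory written by [write_report()].
#' @return Named character vector of md5 sums.
#' @export
report_checksums <- function(outdir) {
  files <- setdiff(list.files(outdir, pattern = "\\.tsv$"), "manifest.tsv")
  sums <- tools::md5sum(file.path(outdir, files))
  stats::setNames(unname(sums), files)
}
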