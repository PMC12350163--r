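#' Simulation configuration
#'
#' Defines a toy genome and the statistical structure of the chromatin and
#' piRNA datasets the pipeline expects: dual- vs single-marked bins,
#' negative-binomial replicate count tracks over a uniform background,
#' stranded piRNA counts with condition-specific fold losses, and
#' low-mappability regions created by exact sequence duplications.
#'
#' @param seed Master seed; every output stream derives its own substream
#'   from it, so adding samples does not perturb existing ones.
#' @param n_sequences Number of chromosome-like sequences.
#' @param sequence_length Length of each chromosome-like sequence (bp).
#' @param bin_size Bin width (bp) used for the truth table.
#' @param duplication_blocks List of `c(length_bp, copies)` pairs; each
#'   block is stamped as exact repeats so downstream mappability drops
#'   below 1 there.
#' @param mark_background_mean Expected fragments per bin in unmarked bins
#'   (and everywhere in the IgG-like background track).
#' @param enrichment_fold Mean multiplier for bins carrying the mark.
#' @param nb_dispersion Negative-binomial dispersion `alpha`
#'   (variance `mu + alpha * mu^2`).
#' @param n_replicates Replicates per track.
#' @param pirna_mean Expected piRNA reads per expressing bin per strand.
#' @param pirna_background_mean Expected stray piRNA reads per
#'   non-expressing bin per strand (most genomic bins produce none).
#' @param knockdown_fold Fold reduction applied to dependent bins under the
#'   matching knockdown (default 8).
#' @param gain_fold Fold increase for the anticorrelated
#'   (gain-under-E(z)-loss) class (default 2).
#' @param fragment_length Chromatin fragment length (bp).
#' @param pirna_read_length piRNA read length (bp).
#' @param mark_state_props Named proportions over
#'   none/K9only/K27only/both for chromosome bins.
#' @param cluster_probs P(dual-strand cluster | mark state): dual-marked
#'   bins preferentially host dual-strand clusters.
#' @param unistrand_prob P(unistrand cluster) for bins without a
#'   dual-strand cluster.
#' @param unistrand_mean Expected piRNA reads per unistrand-cluster bin on
#'   its producing strand. Unistrand/somatic-type clusters are unaffected
#'   by the knockdowns and keep total library size from collapsing when
#'   dual-strand production is lost, as in real ovary small-RNA libraries.
#' @param dependency_props Named proportions over
#'   Rhi_only/Ez_dep/Kipf_dep/both_dep/gain_on_EzKD for dual-strand bins.
#' @param binding_probs P(Rhino-bound | mark state) for bins without a
#'   dual-strand cluster (dual-strand cluster bins are always bound).
#' @param mito_length Length of the terminal mitochondria-like sequence.
#' @param scaffold_length Length of the unplaced-contig-like sequence.
#' @param het_fraction Fraction of each chromosome start annotated as
#'   heterochromatin in the truth compartments.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_sequences = 3L,
                       sequence_length = 1e6,
                       bin_size = 1000L,
                       duplication_blocks = list(c(3000L, 3L)),
                       mark_background_mean = 20,
                       enrichment_fold = 6,
                       nb_dispersion = 0.1,
                       n_replicates = 2L,
                       pirna_mean = 80,
                       pirna_background_mean = 0.01,
                       knockdown_fold = 8,
                       gain_fold = 2,
                       fragment_length = 150L,
                       pirna_read_length = 25L,
                       mark_state_props = c(none = 0.62, K9only = 0.12,
                                            K27only = 0.18, both = 0.08),
                       cluster_probs = c(both = 0.7, K9only = 0.08,
                                         K27only = 0.01, none = 0.002),
                       unistrand_prob = 0.06,
                       unistrand_mean = 200,
                       dependency_props = c(Rhi_only = 0.30, Ez_dep = 0.25,
                                            Kipf_dep = 0.25, both_dep = 0.12,
                                            gain_on_EzKD = 0.08),
                       binding_probs = c(both = 0.85, K9only = 0.45,
                                         K27only = 0.03, none = 0.08),
                       mito_length = 5000L,
                       scaffold_length = 20000L,
                       het_fraction = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$mark_background_mean > 0, cfg$pirna_mean > 0,
            cfg$pirna_background_mean > 0)
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (cfg$knockdown_fold <= 1) stop("knockdown_fold must be > 1")
  if (abs(sum(cfg$mark_state_props) - 1) > 1e-8)
    stop("mark_state_props must sum to 1")
  if (abs(sum(cfg$dependency_props) - 1) > 1e-8)
    stop("dependency_props must sum to 1")
  for (blk in cfg$duplication_blocks) {
    if (length(blk) != 2L) stop("duplication blocks are c(length, copies)")
    if (blk[1] >= cfg$sequence_length)
      stop("duplication block longer than sequence")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Merged runs of selected truth bins as 0-based half-open intervals.
.truth_runs <- function(truth, sel) {
  dt <- truth[sel, c("chrom", "start", "end")]
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  gr <- GenomicRanges::reduce(.as_granges(dt))
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
}

# Deterministic substream seed from the master seed and a string key.
.substream_seed <- function(master, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

.with_substream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(.substream_seed(master, key), kind = "Mersenne-Twister")
  force(expr)
}

#' Simulate a toy genome with a bin-level truth table
#'
#' Random chromosome-like sequences plus a terminal mitochondria-like
#' sequence and an unplaced-contig-like sequence; exact duplication blocks
#' are stamped into the chromosomes so that k-mer mappability drops there.
#' Every bin of the tiling is assigned a mark state, cluster label
#' (dual-strand clusters preferentially in dual-marked bins), knockdown
#' dependency class, Rhino-binding flag and compartment label.
#'
#' @param cfg A [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `truth` (data.table, one
#'   row per bin), `compartments` (interval table) and
#'   `duplicated_regions`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_sequences))
  seq_names <- c(chroms, "Scaffold_sim_1", "chrM_sim")
  seq_lens <- c(rep(cfg$sequence_length, cfg$n_sequences),
                cfg$scaffold_length, cfg$mito_length)
  seqs <- .with_substream(cfg$seed, "genome/base", {
    lapply(seq_lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  })
  names(seqs) <- seq_names

  dup <- list()
  offset <- floor(cfg$sequence_length * 0.55)
  gap <- 500L
  for (i in seq_along(cfg$duplication_blocks)) {
    blk <- cfg$duplication_blocks[[i]]
    L <- as.integer(blk[1]); k <- as.integer(blk[2])
    block_seq <- .with_substream(cfg$seed, sprintf("genome/dup%d", i), {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    })
    for (j in seq_len(k)) {
      chrom <- chroms[((j - 1L) %% cfg$n_sequences) + 1L]
      start <- offset + ((j - 1L) %/% cfg$n_sequences) * (L + gap)
      if (start + L > cfg$sequence_length)
        stop("duplication blocks do not fit in the sequence")
      substr(seqs[[chrom]], start + 1L, start + L) <- block_seq
      dup[[length(dup) + 1L]] <- data.frame(chrom = chrom, start = start,
                                            end = start + L, block = i)
    }
    offset <- offset + ceiling(k / cfg$n_sequences) * (L + gap) + gap
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- seq_names

  compartments <- data.frame(
    chrom = rep(chroms, 2),
    start = c(rep(0, length(chroms)),
              rep(floor(cfg$sequence_length * cfg$het_fraction), length(chroms))),
    end = c(rep(floor(cfg$sequence_length * cfg$het_fraction), length(chroms)),
            rep(cfg$sequence_length, length(chroms))),
    label = rep(c("heterochromatin", "euchromatin"), each = length(chroms))
  )

  bins <- tile_genome(stats::setNames(seq_lens, seq_names), cfg$bin_size)
  bins <- assign_compartment(bins, compartments)
  n <- nrow(bins)
  on_chrom <- bins$chrom %in% chroms

  truth <- .with_substream(cfg$seed, "truth", {
    mark_state <- rep("none", n)
    mark_state[on_chrom] <- sample(names(cfg$mark_state_props), sum(on_chrom),
                                   replace = TRUE, prob = cfg$mark_state_props)
    p_dual <- ifelse(on_chrom, cfg$cluster_probs[mark_state], 0)
    dual <- stats::runif(n) < p_dual
    uni <- !dual & on_chrom & stats::runif(n) < cfg$unistrand_prob
    cluster_label <- ifelse(dual, "dual_strand",
                            ifelse(uni, "unistrand", "none"))
    strand <- rep(".", n)
    strand[uni] <- sample(c("+", "-"), sum(uni), replace = TRUE)
    dependency_class <- rep("none", n)
    dependency_class[dual] <- sample(names(cfg$dependency_props), sum(dual),
                                     replace = TRUE,
                                     prob = cfg$dependency_props)
    rhi_bound <- dual |
      (on_chrom & stats::runif(n) < cfg$binding_probs[mark_state])
    data.table::data.table(
      bin_id = bins$bin_id, chrom = bins$chrom, start = bins$start,
      end = bins$end, mark_state = mark_state,
      cluster_label = cluster_label, strand = strand,
      dependency_class = dependency_class, rhi_bound = rhi_bound,
      compartment = bins$compartment)
  })

  list(genome = genome, truth = truth, compartments = compartments,
       duplicated_regions = if (length(dup)) do.call(rbind, dup)
                            else data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0),
                                            block = integer(0)))
}

# Draw NB counts and place that many fragments uniformly inside each bin.
# Fragments never straddle bin boundaries (placement is constrained) unless
# straddle = TRUE, which lets starts run up to the bin end.
.place_fragments <- function(truth, counts, frag_len, strand = ".",
                             straddle = FALSE) {
  idx <- which(counts > 0L)
  if (length(idx) == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0)))
  reps <- counts[idx]
  chrom <- rep(truth$chrom[idx], reps)
  b_start <- rep(truth$start[idx], reps)
  b_end <- rep(truth$end[idx], reps)
  room <- pmax(b_end - b_start - (if (straddle) 0L else frag_len), 0L) + 1L
  offs <- floor(stats::runif(length(chrom)) * room)
  start <- b_start + offs
  end <- pmin(start + frag_len, if (straddle) b_end + frag_len else b_end)
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         strand = rep(strand, length.out = length(chrom)))
}

.rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate chromatin-mark fragment tracks
#'
#' Per-bin fragment counts are negative-binomial with mean
#' `mark_background_mean` in unmarked bins and `x enrichment_fold` in bins
#' whose mark state includes the mark; fragments are placed uniformly
#' within their bin. An IgG-like background track is drawn at the
#' background mean everywhere; its RNG substream depends only on the
#' replicate, so the same background is shared across marks.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param cfg The [sim_config()].
#' @param mark `"H3K9me3"` or `"H3K27me3"`.
#' @param n_replicates Number of replicates (default from config).
#' @return list with `replicates` (list of fragment data.tables), `counts`
#'   (bins x replicates matrix of drawn counts), and `background` (list
#'   with `replicates` and `counts` for the IgG-like track).
#' @export
simulate_mark_fragments <- function(truth, cfg, mark,
                                    n_replicates = cfg$n_replicates) {
  mark <- match.arg(mark, c("H3K9me3", "H3K27me3"))
  marked <- switch(mark,
                   H3K9me3 = truth$mark_state %in% c("K9only", "both"),
                   H3K27me3 = truth$mark_state %in% c("K27only", "both"))
  mu <- ifelse(marked, cfg$mark_background_mean * cfg$enrichment_fold,
               cfg$mark_background_mean)
  n <- nrow(truth)
  counts <- matrix(0L, n, n_replicates)
  replicates <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    replicates[[r]] <- .with_substream(
      cfg$seed, sprintf("mark/%s/rep%d", mark, r), {
        counts[, r] <- .rnb(n, mu, cfg$nb_dispersion)
        .place_fragments(truth, counts[, r], cfg$fragment_length)
      })
  }
  bg_counts <- matrix(0L, n, n_replicates)
  bg_reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    bg_reps[[r]] <- .with_substream(cfg$seed, sprintf("igg/rep%d", r), {
      bg_counts[, r] <- .rnb(n, cfg$mark_background_mean, cfg$nb_dispersion)
      .place_fragments(truth, bg_counts[, r], cfg$fragment_length)
    })
  }
  list(replicates = replicates, counts = counts,
       background = list(replicates = bg_reps, counts = bg_counts))
}

# Expected piRNA mean per bin for one strand under a condition.
.pirna_mu <- function(truth, cfg, condition, strand) {
  dual <- truth$cluster_label == "dual_strand"
  uni <- truth$cluster_label == "unistrand" & truth$strand == strand
  mu <- rep(cfg$pirna_background_mean, nrow(truth))
  mu[uni] <- cfg$unistrand_mean
  mu[dual] <- cfg$pirna_mean
  dc <- truth$dependency_class
  kf <- cfg$knockdown_fold
  if (condition %in% c("EzKD", "doubleKD")) {
    mu[dual & dc %in% c("Ez_dep", "both_dep")] <-
      mu[dual & dc %in% c("Ez_dep", "both_dep")] / kf
    mu[dual & dc == "gain_on_EzKD"] <-
      mu[dual & dc == "gain_on_EzKD"] * cfg$gain_fold
  }
  if (condition %in% c("kipfKD", "doubleKD")) {
    mu[dual & dc %in% c("Kipf_dep", "both_dep")] <-
      mu[dual & dc %in% c("Kipf_dep", "both_dep")] / kf
  }
  if (condition == "rhiKD") mu[dual] <- mu[dual] / kf
  mu
}

#' Simulate stranded piRNA read sets under a knockdown condition
#'
#' Dual-strand cluster bins emit reads on both strands at `pirna_mean` in
#' control; under `EzKD` the E(z)-dependent (and both-dependent) bins are
#' divided by `knockdown_fold` and the anticorrelated class is multiplied
#' by `gain_fold`; `kipfKD` divides the Kipf-dependent (and
#' both-dependent) bins; `doubleKD` applies both rules; `rhiKD` divides
#' all dual-strand bins. Unistrand cluster bins emit one strand only and
#' are unaffected by every condition.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param cfg The [sim_config()].
#' @param condition One of control, EzKD, kipfKD, doubleKD, rhiKD.
#' @param n_replicates Number of replicates.
#' @param stream_tag Extra tag mixed into the RNG substream, so distinct
#'   experiments (e.g. depletion strategies) sharing a condition draw
#'   independent data.
#' @return list with `replicates` (list of stranded fragment data.tables),
#'   `counts_plus`, `counts_minus` (bins x replicates matrices).
#' @export
simulate_pirna_reads <- function(truth, cfg, condition,
                                 n_replicates = cfg$n_replicates,
                                 stream_tag = "") {
  condition <- match.arg(condition,
                         c("control", "EzKD", "kipfKD", "doubleKD", "rhiKD"))
  mu_p <- .pirna_mu(truth, cfg, condition, "+")
  mu_m <- .pirna_mu(truth, cfg, condition, "-")
  n <- nrow(truth)
  counts_plus <- matrix(0L, n, n_replicates)
  counts_minus <- matrix(0L, n, n_replicates)
  replicates <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    replicates[[r]] <- .with_substream(
      cfg$seed, sprintf("pirna/%s/%s/rep%d", condition, stream_tag, r), {
        counts_plus[, r] <- .rnb(n, mu_p, cfg$nb_dispersion)
        counts_minus[, r] <- .rnb(n, mu_m, cfg$nb_dispersion)
        rbind(.place_fragments(truth, counts_plus[, r],
                               cfg$pirna_read_length, "+"),
              .place_fragments(truth, counts_minus[, r],
                               cfg$pirna_read_length, "-"))
      })
  }
  list(replicates = replicates, counts_plus = counts_plus,
       counts_minus = counts_minus)
}

#' Simulate the multi-strategy knockdown design for dependency calling
#'
#' Emulates a cohort in which Rhi dependency is assessed across three
#' depletion strategies, E(z) dependency across two drivers and Kipf
#' dependency across a knockdown and a knockout, each strategy with its own
#' control arm.
#'
#' @param truth,cfg As elsewhere.
#' @return Nested list: `$rhi`, `$ez`, `$kipf`, each a named list of
#'   strategies with `control` and `depleted` simulation objects (from
#'   [simulate_pirna_reads()]).
#' @export
simulate_knockdown_design <- function(truth, cfg) {
  build <- function(condition, strategies) {
    out <- lapply(strategies, function(tag) {
      list(control = simulate_pirna_reads(truth, cfg, "control",
                                          stream_tag = tag),
           depleted = simulate_pirna_reads(truth, cfg, condition,
                                           stream_tag = tag))
    })
    stats::setNames(out, strategies)
  }
  list(rhi = build("rhiKD", c("pTOsk_KD", "MTD_KD", "rhi_KO")),
       ez = build("EzKD", c("nos_KD", "pTOsk_KD")),
       kipf = build("kipfKD", c("MTD_KD", "kipf_KO")))
}

#' Total piRNA counts (both strands) per bin and replicate
#'
#' @param sim A result of [simulate_pirna_reads()].
#' @return Integer matrix bins x replicates.
#' @export
pirna_total_counts <- function(sim) sim$counts_plus + sim$counts_minus

#' Simulated peak calls
#'
#' Peaks are the merged runs of truly marked bins (per mark, identical
#' across replicates: the generator is noise-free at the peak level), plus
#' Rhino-binding peak sets for the peak-dependency analysis: control
#' replicates carry fold-enrichment `enrichment_fold` at bound bins plus
#' two sub-threshold decoy peaks, the scaffold sequence carries decoy
#' peaks (to exercise unplaced-contig exclusion), the rhi-knockdown set
#' retains one residual peak (to exercise the present-in-rhiKD exclusion)
#' and the kipf-knockdown set retains peaks only where binding does not
#' require Kipferl.
#'
#' @param truth,cfg As elsewhere.
#' @param n_replicates Number of replicates.
#' @return list with `marks` (per mark, list of per-replicate peak
#'   tables) and `rhi` (list with `control` per-replicate sets, `rhikd`,
#'   `kipfkd`).
#' @export
simulate_peak_calls <- function(truth, cfg, n_replicates = cfg$n_replicates) {
  runs_of <- function(sel) .truth_runs(truth, sel)
  with_cols <- function(p, fold) {
    p$fold_enrichment <- rep(fold, length.out = nrow(p))
    p$qvalue <- 1e-4
    p
  }
  marks <- lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"), function(mk) {
    sel <- switch(mk, H3K9me3 = truth$mark_state %in% c("K9only", "both"),
                  H3K27me3 = truth$mark_state %in% c("K27only", "both"))
    pk <- with_cols(runs_of(sel), cfg$enrichment_fold)
    lapply(seq_len(n_replicates), function(r) pk)
  })

  bound <- runs_of(truth$rhi_bound)
  decoy_bins <- utils::head(which(!truth$rhi_bound &
                                    truth$chrom == truth$chrom[1]), 2)
  decoys <- with_cols(truth[decoy_bins, c("chrom", "start", "end")],
                      cfg$enrichment_fold / 3)
  scaffold <- with_cols(
    data.table::data.table(chrom = "Scaffold_sim_1",
                           start = c(1000L, 5000L), end = c(1500L, 5600L)),
    cfg$enrichment_fold)
  control <- lapply(seq_len(n_replicates), function(r)
    rbind(with_cols(bound, cfg$enrichment_fold), decoys, scaffold))

  dual <- truth$cluster_label == "dual_strand"
  first_dual <- which(dual & truth$rhi_bound)[1]
  rhikd <- with_cols(truth[first_dual, c("chrom", "start", "end")], 2)
  kipf_independent_bound <- truth$rhi_bound &
    (!dual | truth$dependency_class %in% c("Rhi_only", "Ez_dep", "gain_on_EzKD"))
  kipfkd <- with_cols(runs_of(kipf_independent_bound), cfg$enrichment_fold)

  list(marks = marks,
       rhi = list(control = control, rhikd = rhikd, kipfkd = kipfkd))
}

#' Simulate the full synthetic cohort
#'
#' @param cfg A [sim_config()].
#' @return list with `config`, `genome`, `truth`, `compartments`,
#'   `duplicated_regions`, `marks` (per mark), `pirna` (knockdown design)
#'   and `peaks`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  g <- simulate_genome(cfg)
  marks <- lapply(c(H3K9me3 = "H3K9me3", H3K27me3 = "H3K27me3"),
                  function(mk) simulate_mark_fragments(g$truth, cfg, mk))
  list(config = cfg, genome = g$genome, truth = g$truth,
       compartments = g$compartments,
       duplicated_regions = g$duplicated_regions,
       marks = marks,
       pirna = simulate_knockdown_design(g$truth, cfg),
       peaks = simulate_peak_calls(g$truth, cfg))
}

#' Read a stored simulation configuration
#'
#' Round-trips the YAML written by [write_fixture()] back into a validated
#' [sim_config()].
#'
#' @param path Path to a `config.yaml` from a fixture directory.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$duplication_blocks <- lapply(raw$duplication_blocks, as.integer)
  for (nm in c("mark_state_props", "cluster_probs", "dependency_props",
               "binding_probs"))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}

#' Write a cohort to disk as plain-text fixture files
#'
#' FASTA genome, chrom.sizes, BED6 fragment files per sample/replicate,
#' BED6+2 peak files, truth TSV, compartment BED and the configuration
#' (YAML). Regenerating with the same config yields byte-identical files.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(cohort, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("cannot write to ", outdir)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(cohort$genome, p("genome.fa"), width = 80L)
  writeLines(sprintf("%s\t%d", names(cohort$genome),
                     Biostrings::width(cohort$genome)), p("chrom.sizes"))
  data.table::fwrite(cohort$truth, p("truth.tsv"), sep = "\t")
  data.table::fwrite(cohort$compartments, p("compartments.tsv"), sep = "\t")
  for (mk in names(cohort$marks)) {
    sim <- cohort$marks[[mk]]
    for (r in seq_along(sim$replicates))
      write_fragments_bed(sim$replicates[[r]],
                          p(sprintf("%s_rep%d.bed", mk, r)), mk)
    for (r in seq_along(sim$background$replicates))
      write_fragments_bed(sim$background$replicates[[r]],
                          p(sprintf("IgG_rep%d.bed", r)), "IgG")
  }
  for (pert in names(cohort$pirna)) {
    for (strat in names(cohort$pirna[[pert]])) {
      for (arm in c("control", "depleted")) {
        sim <- cohort$pirna[[pert]][[strat]][[arm]]
        for (r in seq_along(sim$replicates))
          write_fragments_bed(
            sim$replicates[[r]],
            p(sprintf("pirna_%s_%s_%s_rep%d.bed", pert, strat, arm, r)),
            "pirna")
      }
    }
  }
  for (mk in names(cohort$peaks$marks))
    for (r in seq_along(cohort$peaks$marks[[mk]]))
      write_peaks_bed(cohort$peaks$marks[[mk]][[r]],
                      p(sprintf("peaks_%s_rep%d.bed", mk, r)))
  for (r in seq_along(cohort$peaks$rhi$control))
    write_peaks_bed(cohort$peaks$rhi$control[[r]],
                    p(sprintf("peaks_rhi_control_rep%d.bed", r)))
  write_peaks_bed(cohort$peaks$rhi$rhikd, p("peaks_rhi_rhiKD.bed"))
  write_peaks_bed(cohort$peaks$rhi$kipfkd, p("peaks_rhi_kipfKD.bed"))
  dual <- .truth_runs(cohort$truth, cohort$truth$cluster_label == "dual_strand")
  uni <- .truth_runs(cohort$truth, cohort$truth$cluster_label == "unistrand")
  dual$name <- sprintf("dual_%d", seq_len(nrow(dual)))
  uni$name <- sprintf("uni_%d", seq_len(nrow(uni)))
  data.table::fwrite(dual, p("clusters_dual.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(uni, p("clusters_unistrand.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  cfg <- unclass(cohort$config)
  cfg$duplication_blocks <- lapply(cfg$duplication_blocks, as.integer)
  for (nm in c("mark_state_props", "cluster_probs", "dependency_props",
               "binding_probs"))
    cfg[[nm]] <- as.list(cfg[[nm]])   # keep names through YAML
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(outdir)
}
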