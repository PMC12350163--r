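# Independent brute-force oracles used to pin down the fast implementations.

# Tie-corrected Mann-Whitney AUC via mid-ranks.
oracle_auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)                     # mid-ranks handle ties
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Two-sided Fisher p by enumerating every table with the observed margins,
# point probabilities from log-binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; k <- a + c; n_tot <- a + b + c + d
  lo <- max(0L, k - (n_tot - m)); hi <- min(m, k)
  logp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(n_tot - m, k - x) - lchoose(n_tot, k), 0)
  obs <- lchoose(m, a) + lchoose(n_tot - m, k - a) - lchoose(n_tot, k)
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

# Fragment counting by checking every (fragment, bin) pair.
oracle_count_fragments <- function(bins, frags, frac = 0.5, strand = "both") {
  counts <- stats::setNames(integer(nrow(bins)), bins$bin_id)
  for (i in seq_len(nrow(frags))) {
    if (strand != "both" && frags$strand[i] != strand) next
    flen <- frags$end[i] - frags$start[i]
    for (j in seq_len(nrow(bins))) {
      if (frags$chrom[i] != bins$chrom[j]) next
      ov <- min(frags$end[i], bins$end[j]) - max(frags$start[i], bins$start[j])
      if (ov >= frac * flen) counts[j] <- counts[j] + 1L
    }
  }
  counts
}

# k-mer mappability by tallying occurrences over the forward k-mers of the
# genome and of its reverse complement (a palindromic k-mer appears in both
# lists at the same placement, so its combined count is halved).
oracle_mappability <- function(genome, n) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < n) character(0) else substring(s, 1:(L - n + 1), n:L)
  }
  seqs <- vapply(seq_along(genome), function(i) as.character(genome[[i]]), "")
  fwd <- lapply(seqs, kmers_of)
  rcl <- lapply(seqs, function(s) kmers_of(revcomp(s)))
  tab <- table(c(unlist(fwd), unlist(rcl)))
  unique_start <- lapply(fwd, function(ks) {
    vapply(ks, function(k) {
      if (grepl("[^ACGT]", k)) return(FALSE)
      occ <- tab[[k]]
      if (identical(k, revcomp(k))) occ <- occ / 2
      occ == 1
    }, TRUE, USE.NAMES = FALSE)
  })
  names(unique_start) <- names(genome)
  per_position <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[[i]])
    u <- unique_start[[i]]
    vapply(seq_len(L), function(p) {
      js <- max(1, p - n + 1):min(p, length(u))
      if (length(u) == 0 || js[1] > length(u)) return(0)
      min(sum(u[js]) / n, 1)
    }, 0)
  })
  names(per_position) <- names(genome)
  list(unique_start = unique_start, per_position = per_position)
}

oracle_bin_mappability <- function(bins, unique_start) {
  vapply(seq_len(nrow(bins)), function(j) {
    u <- unique_start[[bins$chrom[j]]]
    starts0 <- seq_along(u) - 1L
    sum(u[starts0 >= bins$start[j] & starts0 < bins$end[j]]) /
      (bins$end[j] - bins$start[j])
  }, 0)
}

random_genome <- function(len, n_seq = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- vapply(seq_len(n_seq), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- sprintf("s%d", seq_len(n_seq))
  g
}

random_fragments <- function(n, seqlens, max_len = 120) {
  chrom <- sample(names(seqlens), n, TRUE)
  len <- sample(10:max_len, n, TRUE)
  start <- floor(runif(n) * pmax(seqlens[chrom] - len, 1))
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + len),
                         strand = sample(c("+", "-"), n, TRUE))
}

# Small simulation config for fast unit tests.
tiny_sim_config <- function(duplication_blocks = list(c(2000L, 2L)), ...) {
  sim_config(n_sequences = 2L, sequence_length = 60000, bin_size = 1000L,
             duplication_blocks = duplication_blocks,
             mito_length = 3000L, scaffold_length = 8000L, ...)
}
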