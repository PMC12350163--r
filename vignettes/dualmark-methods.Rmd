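---
title: "Methods: bin-level analysis of dual-marked chromatin at piRNA source loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-level analysis of dual-marked chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmark)
```

# Scope and model

`dualmark` quantifies chromatin-mark and small-RNA signal on a fixed
genomic bin grid and asks three questions about piRNA source loci in fly
germ cells: (1) how well H3K9me3, H3K27me3, and their combination predict
dual-strand piRNA cluster bins (ROC/AUC); (2) how strongly Rhino binding
associates with each combinatorial mark state (stratified odds ratios);
and (3) which loci lose piRNA output when Rhino, E(z) or Kipferl is
depleted (fold-change classification of bins and peaks). All operations
act on explicit, unit-tested rules; a synthetic-data generator with a
truth table closes the loop so the full chain is verified end-to-end.

# Binning and mappability

Bins are non-overlapping tiles (default 1 kb; the final shorter tail of a
sequence is kept) or sliding windows (10 kb window, 5 kb step; windows
shorter than 5 kb are flagged and removed by the explicit filter step —
the raw pre-filter window count is reported separately, since both
quantities are meaningful).

Mappability stands in for unique short-read alignability using exact
k-mer matching: an *n*-mer is unique iff its sequence occurs exactly once
in the genome over both strands. A palindromic *n*-mer equals its own
reverse complement, so its two strand orientations are one placement and
are counted once. Any *n*-mer containing a non-ACGT symbol is
non-unique. Per-position mappability divides the number of overlapping
unique *n*-mers by *n* even near sequence ends (where fewer than *n*
*n*-mers exist), which slightly penalizes the outermost `n - 1` positions;
per-bin mappability divides the unique *n*-mer *starts* in the bin by the
bin length. Defaults: `n = 100` for chromatin fragments, 26 for small-RNA
reads. Bins with mappability below 0.2 (strictly) are removed, as are
mitochondrial sequences. The implementation (canonical-k-mer counting) is
pinned to an independent brute-force oracle on randomized genomes in the
test suite.

Compartment labels (euchromatin / heterochromatin / other) are assigned by
bin midpoint, which avoids double-labelling where a bin straddles a
boundary; published 1-based inclusive compartment coordinates for dm6 are
converted once, at entry, to the package's 0-based half-open convention
(`dmel_compartments()`).

# Counting, background subtraction, normalization

Bin-level read counting uses the >= 50%-of-fragment overlap rule, ties
included: a fragment split exactly in half across a bin boundary counts in
both bins. Stranded libraries are counted per strand. On the 50 bp
background-subtraction grid this rule would be meaningless (a 150 bp
fragment can never lie half inside a 50 bp window), so window
quantification is coverage-style: any-overlap counts
(`window_coverage()`). This mirrors standard practice, where bin counting
and browser-track/window coverage are different operations.

Background subtraction follows the signal-extraction-scaling contract:
windows are ordered by signal, the lowest 50% (configurable) define the
scale `s = sum(signal)/sum(background)` — i.e., the background is matched
where enrichment is absent — then `max(signal - s * background, 0)` per
window, and the per-bin value is the mean over windows fully inside the
bin. `s` is clamped to `[1e-3, 1e3]`; an all-zero background yields
`s = 1` with a warning. The exact sampling parameters of the original SES
estimator are not part of the contract; only its intent is.

Normalizations: mappability-corrected FPKM
(`count * 1e9 / (library * length * mappability)`), cpm, median-of-ratios
size factors (cross-checked against DESeq2 in the tests),
`log2((t + pc)/(c + pc))` with a default pseudocount of 0.01 on
normalized values, the display transform `log10(min(x, cap) + 1)` with
caps 300 (1 kb bins) / 200 (10 kb), and the minimum-of-strands statistic
that zeroes unistrand signatures.

# Classification statistics

**ROC/AUC.** Bins are sorted by score descending; tied scores form one
threshold, so ties contribute a diagonal segment rather than an
optimistic per-item step. AUC is the trapezoid over (FPR, TPR) with the
(0,0) and (1,1) endpoints, which equals the tie-corrected Mann–Whitney
statistic — the property-based tests assert exactly that on hundreds of
randomized instances, plus invariance under monotone transforms and the
`AUC(s) + AUC(-s) = 1` symmetry. Positives are bins overlapping the
cluster annotation of interest; the combined predictor is the arithmetic
mean of the two per-bin mark-enrichment tracks (the same values used for
the single-mark ROCs, so the scales are comparable).

**Overlap enrichment.** Presence calls (>= 1 bp bin/peak overlap,
half-open semantics) feed 2x2 tables. The odds ratio is the sample
estimate `ad/bc` with Haldane's 0.5 added to all cells when any cell is
zero — deliberately *not* the conditional-MLE estimate that
`stats::fisher.test()` prints, which differs for extreme tables; the
p-value is the standard two-sided Fisher exact probability (sum of
hypergeometric point probabilities not exceeding the observed one, with a
`1 + 1e-7` relative tolerance for floating-point ties) and is verified to
1e-12 against an exhaustive enumeration oracle. The four-way mark-state
analysis computes one table per stratum: binding versus membership in
that stratum against all other bins.

**Consensus peaks** union-merge replicate peaks and keep merged intervals
supported by >= 2 replicates (all peaks with a single replicate).
Chained overlaps merge transitively with cumulative support.

**Level groups.** Group 1 holds zero-level bins; the remaining bins are
sorted and 15 equidistant rank breakpoints (including the extremes) are
taken at ranks `round(i (m-1)/14) + 1`. Consecutive distinct breakpoint
values define half-open intervals, the last closed at the top, so tied
data give fewer (never empty) groups and the grouping is always a
partition. With levels `1..15` this yields 13 singleton groups plus one
group holding the top two values — with 15 values and 14 intervals a
perfect one-per-group split is impossible, and closing the last interval
is the only choice that loses no bins.

# Dependency classification

Fold *loss* is `control / depleted`. Within a depletion strategy,
replicates are averaged per arm; the pseudocount is applied to the
rep-averaged cpm; the per-bin statistic is the **mean of the per-strategy
ratios** (a ratio-of-means mode exists for sensitivity checks). Bins are
Rhino-dependent at mean loss strictly > 2 across the rhi-depletion
strategies, and E(z)/Kipferl/both-dependent at mean loss >= 4 under the
respective depletions; Rhi-dependent bins failing both are "neither"
(Rhi-only). The pseudocount default is half a read converted to cpm for
the library (`cpm_pseudocount()`), so it scales with depth: with a fixed
tiny pseudocount, a single stray read in an otherwise empty bin would
produce an enormous "fold change" and spurious dependency calls.

Peak-level Kipferl dependency: per-replicate control peaks with fold
enrichment >= 3 are union-merged into a high-confidence set; peaks on
unplaced contigs (configurable name pattern — default flags names
containing "Scaffold"/"rand" or lacking a "chr" prefix, since assembly
naming varies) or overlapping any rhi-knockdown peak by >= 1 bp are
excluded with a recorded reason; the rest are Kipferl-independent iff
they overlap a Kipferl-knockdown peak.

The six-group delta analysis ranks bins by the primary signal change,
splits them into equal-size groups (remainder to the lowest-rank groups;
ties broken by bin id so the partition is deterministic even for constant
input) and reports each responder track's mean change per group,
optionally restricted to bins whose secondary mark exceeds the 90th
percentile of euchromatic bins. Equal-size rank grouping (rather than
thresholding the change into ranges) is used because it is
parameter-free and well-defined for any distribution of changes.

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not any particular genome:

- **Genome**: 3 chromosome-like sequences of 1 Mb of i.i.d. ACGT, plus a
  5 kb mitochondria-like sequence (exclusion testing) and a 20 kb
  unplaced-contig-like sequence (peak-exclusion testing). A 3 kb block
  stamped as 3 exact copies creates a low-mappability region caught by
  the 20% filter. All randomness flows through named substreams derived
  from the master seed (one per sample/replicate/condition), so adding a
  track never perturbs existing ones and fixture files regenerate
  byte-identically.
- **Bin states**: mark states drawn i.i.d. with proportions
  none/K9only/K27only/both = 0.62/0.12/0.18/0.08 — dual-marked chromatin
  is the rarest state, as in real heterochromatin. Dual-strand clusters
  occur preferentially in dual-marked bins
  (P(dual | both) = 0.7 against 0.08/0.01/0.002 elsewhere): the
  combinatorial-code signal the classifier is supposed to find is a
  property of the simulation's conditional structure, not of any tuned
  margin. Rhino binding covers all dual-strand bins plus
  state-dependent extras (0.85/0.45/0.03/0.08), which yields the
  both > K9-only > 1 > K27-only odds-ratio ordering structurally.
- **Counts**: negative binomial with variance `mu + alpha mu^2`,
  `alpha = 0.1` — a standard sequencing-overdispersion model and a
  mid-range dispersion for replicate count tracks. Marked bins have mean
  `20 x 6` fragments against a background of 20; fragments are 150 bp,
  placed uniformly and never straddling bin boundaries by default, so
  re-counting recovers the drawn counts exactly and generator
  correctness is separable from counting-rule semantics (a flag enables
  straddling for overlap-rule tests).
- **piRNA libraries**: dual-strand bins emit ~80 reads per strand;
  unistrand bins emit one strand at a higher mean (200), emulating the
  large Rhino-independent share of real ovary libraries (somatic-type /
  unistrand clusters); other bins emit almost nothing (mean 0.01 per
  strand — most genomic bins produce no uniquely mapping piRNAs). The
  unistrand mass matters: piRNA abundances are compared as cpm, and if
  knockdown-sensitive clusters carried the entire library, depletion
  would shrink the library itself and cpm renormalization would erase
  the fold signal. Real libraries retain a Rhi-independent read mass;
  early versions of the generator without it produced cpm fold-changes
  near 1 for all bins, which is a failure of emulation, not of the
  classifier.
- **Knockdowns**: E(z)- and both-dependent bins lose 8-fold under E(z)
  depletion, Kipferl- and both-dependent under Kipferl depletion (both
  rules under the double knockdown, so both-dependent bins lose 64-fold
  there), all dual-strand bins lose 8-fold under rhi depletion, and an
  anticorrelated class gains 2-fold under E(z) loss. The cohort builder
  mirrors a multi-driver design (three rhi-depletion strategies, two
  E(z) drivers, two Kipferl perturbations; two replicates per arm),
  because the classifier averages fold-changes across strategies.
  Effect sizes are free parameters of the simulation, not estimates of
  real losses.
- **Peaks** are the merged runs of truly marked (or bound) bins,
  identical across replicates — peak calling itself is upstream of this
  package, so peak inputs are noise-free by design; decoy peaks below
  the fold threshold, scaffold peaks and one rhi-knockdown-persistent
  peak exercise each exclusion rule.

What passing tests do **not** show about real data: the generator has no
repeat families or alignment artifacts (mappability loss is exact
duplication only), no fragment-length or GC structure, no peak-caller
noise or boundary error, no batch effects, and i.i.d. bin states rather
than domain-scale autocorrelation. Recovery rates on the cohort certify
the pipeline's rules, not expected performance on tissue data.

# Problem sizes and runtime choices

The default cohort is ~3 Mb / ~3,000 bins with 26-mer mappability — large
enough that each dependency class holds dozens of bins (so >= 95%
per-class recovery is a meaningful bar) while a full end-to-end run takes
about a minute. Unit tests use smaller genomes (60-300 kb) and oracle
checks run on hundreds of randomized toy instances of length <= 300 with
`n <= 8`, where exhaustive enumeration is instant. The acceptance script
regenerates everything from scratch at the caller's seed.

# Known limitations

- The exact-match uniqueness definition of mappability approximates
  aligner behaviour; mismatch-tolerant aligners would call slightly more
  positions mappable.
- The dm6 size table bundled with the package covers the eight assembled
  molecules only, so genome-wide bin totals computed from it exclude
  unplaced scaffolds.
- The SES scale factor reproduces the contract (match background where
  enrichment is absent) with a fixed lowest-fraction parameter, not the
  original estimator's sampling scheme.
- Odds ratios are reported raw, without multiple-testing adjustment
  across strata, matching how such enrichments are conventionally
  presented.
- Whether piRNA fold-changes are best computed on cpm or FPKM is
  analysis-dependent; cpm is the default for dependency classification
  and FPKM (mappability-corrected) for level displays, both exposed in
  the configuration.
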