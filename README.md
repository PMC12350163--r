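# dualmark

Bin-level chromatin analysis of H3K9me3/H3K27me3 dual-marked domains at
piRNA source loci.

In *Drosophila* germ cells, the HP1-family protein Rhino (Rhi) marks
dual-strand piRNA clusters and licenses piRNA production from them; Rhi
recruitment depends on chromatin state, and loci carrying **both** H3K9me3
and H3K27me3 are its preferred substrates. Testing that idea genome-wide
requires a chain of unglamorous but error-prone steps: tiling the genome
into bins, correcting for alignability, counting fragments under explicit
overlap and strand rules, subtracting antibody background, ranking bins by
mark signal to ask how well marks *predict* cluster membership, measuring
binding/mark association as odds ratios, and classifying loci by how much
piRNA output they lose when Rhi, E(z) (the H3K27 methyltransferase) or
Kipferl (a Rhi co-factor) is depleted.

`dualmark` implements that chain as a tested R package, together with a
synthetic-data generator that produces a toy genome, CUT&RUN-like fragment
tracks, stranded piRNA libraries under a panel of knockdowns, peak calls
and a machine-readable truth table — so every stage can be verified
end-to-end with known ground truth, without any external sequencing data.
It is aimed at people building or auditing piRNA-cluster / chromatin-state
pipelines who need the individual rules to be exact and testable.

## The core quantities

- **Mappability.** For read length *n*, an *n*-mer is unique iff its
  sequence occurs exactly once in the genome considering both strands (a
  palindromic *n*-mer counts its two orientations as one placement).
  Per-position mappability is (# unique *n*-mers overlapping the
  position)/*n*; per-bin mappability is (# unique *n*-mer starts in the
  bin)/(bin length). Bins under 20% mappability are excluded.
- **Counting.** A fragment counts toward a bin iff the overlap covers at
  least half the fragment (ties included, so an exactly split fragment
  counts in both bins); piRNA libraries are counted per strand. Fine
  window grids (50 bp) for background subtraction use coverage-style
  counting instead, with an SES-type scale factor
  `s = sum(signal_low) / sum(background_low)` estimated over the
  lowest-signal half of the windows, subtraction, and clamping at zero.
- **Normalization.** `FPKM = count * 1e9 / (library * bin_length *
  mappability)`; `cpm = count * 1e6 / library`; median-of-ratios size
  factors; the display transform `log10(min(x, cap) + 1)`; and the
  minimum-of-strands statistic that suppresses unistrand signal.
- **Classification.** ROC curves rank bins by mark signal with tied
  scores grouped at one threshold; AUC is the trapezoid over (FPR, TPR)
  and equals the tie-corrected Mann–Whitney statistic. The combined
  predictor is the mean of the two mark tracks. Binding/mark association
  is the sample odds ratio `ad/bc` (Haldane-corrected when a cell is
  empty) with a two-sided Fisher exact p.
- **Dependency.** A bin is Rhi-dependent if mean piRNA cpm fold-loss
  `(control + pc) / (depleted + pc)` across depletion strategies exceeds
  2; Rhi-dependent bins are E(z)- and/or Kipferl-dependent at >= 4-fold
  mean loss. High-confidence Rhi peaks (>= 3-fold enrichment, merged
  across control replicates; unplaced contigs and peaks persisting in
  *rhi* knockdown excluded) are Kipferl-independent iff they retain a
  peak under Kipferl depletion.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic cohort (three 1 Mb chromosomes, ~3,000 1 kb bins, seed 42):

```sh
Rscript analysis/01_simulate.R     # fixture + truth table
Rscript analysis/02_binning.R      # tiling, 26-mer mappability, filtering
Rscript analysis/03_quantify.R     # window counts, SES subtraction, piRNA cpm
Rscript analysis/04_classify.R     # AUC, odds ratios, Venn, level groups
Rscript analysis/05_dependency.R   # Rhi / E(z) / Kipferl dependency calls
Rscript analysis/06_report.R       # orchestrated re-run + recovery report
```

Stage 6 prints, for the default seed:

```
AUC matrix:
       target H3K27me3 H3K9me3 combined_mean
  dual_strand    0.821   0.916         0.948
    unistrand    0.504   0.475         0.477

Odds ratios (Rhino binding vs mark state):
  stratum   a   b    c    d odds_ratio  p_value
  K27only  21 529  507 1954      0.153 3.88e-26
   K9only 176 374  180 2281      5.963 1.04e-47
     both 214 336    9 2452    173.521 2.80e-161
  neither 139 411 1765  696      0.133 2.60e-90

Rhi dependency recovery: sensitivity 100.0%, specificity 100.0%
Dependency label recovery: 99.5% of 182 Rhi-dependent bins
```

Read: the mean of the two mark tracks separates dual-strand cluster bins
better than either mark alone (AUC 0.948 vs 0.916 / 0.821); simulated
Rhino binding is most enriched where both marks co-occur (OR 174), present
but weaker at H3K9me3-only bins (OR 6.0), and depleted at H3K27me3-only
bins (OR 0.15); and the knockdown classifier recovers the simulated
dependency labels almost perfectly at realistic depth. Unistrand clusters,
by design, are not predicted by either mark (AUC ~ 0.5).

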