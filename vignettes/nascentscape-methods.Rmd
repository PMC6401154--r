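---
title: "Methods: quantifying and interpreting nascent transcription with nascentscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and interpreting nascent transcription with nascentscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentscape)
library(dplyr)
```

## Why nascent signal

Run-on sequencing (GRO-seq) captures transcriptionally engaged polymerase,
so its coverage measures transcription *rate* rather than steady-state RNA
abundance. Two consequences drive this package's design. First, unstable
transcripts — primary miRNA transcripts, many lncRNAs and eRNAs — are
visible at their genomic loci even though they barely appear in RNA-seq.
Second, a polymerase initiated at any transcription start site (TSS)
produces signal along the whole gene body downstream of that TSS, so at a
locus with several alternative TSSs the coverage *accumulates* in the 5' to
3' direction: the segment between two adjacent TSSs carries the polymerases
of every TSS upstream of it. The TSS-switching statistic below is built on
exactly this property.

`nascentscape` takes strand-specific coverage tracks (bedGraph, one file
per strand per sample), a transcript annotation, histone-mark peak sets,
super-enhancer intervals, a genome FASTA, a PWM set and flat gene-to-GO and
miRNA-to-target tables, and produces: expression matrices, differential
transcription calls, alternative-TSS activity and switching calls, lncRNA
chromatin classes, guilt-by-association GO transfer, hub-miRNA summaries
and motif-enrichment/TF-expression correlations. A bundled generator
(`simulate_bundle()`) produces all of these inputs with machine-readable
ground truth, so every stage is testable end to end without external data.

## Quantification

The count of a feature is the summed base-resolution coverage over its span
on its strand; FPKM divides by feature length in kb and library size in
millions (`quantify()`). RPKM and FPKM are treated as the same quantity.
The library size is the total signal in the sample's two strand tracks —
the nascent analogue of total mapped reads. Because FPKM is linear in
coverage and inversely linear in depth and length, any global rescaling of
the tracks cancels in every downstream ratio; this is asserted as a test
invariant rather than assumed.

Per-library FPKM carries a composition effect: when regulation is
asymmetric or graded, the more strongly transcribed condition dilutes every
feature's FPKM. `normalize_expression()` removes it by rescaling each
sample with its median-of-ratios size factor (the same correction
`de_test()` applies internally), and the pipeline uses it wherever group
means are compared directly, e.g. the TF expression panels correlated with
motif enrichment.

Features are kept when FPKM exceeds 1 in at least one sample
(`filter_expressed()`, strict inequality). Heatmap-style displays use
per-row min-max scaling to $[-1, 1]$ (`row_normalize()`); constant rows map
to zero rather than NaN. Whole spans are counted by default; GRO-seq
promoter-proximal pausing can be excluded by quantifying on trimmed
features if desired, but no exclusion is applied by default.

## Differential transcription

`de_test()` compares two groups of replicates per feature:

1. **Normalization.** Counts are brought to equal effective library sizes
   by median-of-ratios scaling (the DESeq-style size factor). A plain
   total-count scaling is *not* used because planted (or real) asymmetric
   regulation shifts the totals — with 25% of features changed 8-fold, a
   total-count normalizer would push every null feature ~0.8 log2 units off
   zero, destroying both fold-change accuracy and type-I control. The
   median ratio is robust as long as most features are unchanged.
2. **Dispersion.** A single common negative-binomial dispersion
   $\phi$ (variance $\mu + \phi\mu^2$) is estimated by method of moments on
   within-group residuals, pooled across features:
   $\hat\phi = \mathrm{median}_f\, \max\!\left(0, (s_f^2 - m_f)/m_f^2\right)$.
   No tagwise shrinkage is attempted; with a handful of replicates and a
   planted common dispersion, the median-of-moments estimator is unbiased
   enough (tests require it to land in $[0.1, 0.3]$ when the truth is 0.2)
   and the exact test below is insensitive to modest misestimation.
3. **Exact conditional test.** Conditional on the grand total $T$ of the
   two group sums, the first group's sum follows the distribution induced
   by two NB sums with sizes $n_g/\phi$ and means $n_g\,T/(n_1+n_2)$. The
   two-sided p-value sums the probabilities of all splits no more probable
   than the observed one (relative tie tolerance $10^{-7}$, the same
   convention as `binom.test`). At $\phi = 0$ the conditional law is exactly
   Binomial$(T,\, n_1/(n_1+n_2))$, and the test equals the exact two-sided
   binomial test to machine precision — a limit the suite verifies, along
   with agreement with a conditional distribution built by brute-force
   numeric convolution of per-replicate pmfs.
4. **Multiplicity and status.** Benjamini–Hochberg across features
   (`bh_adjust()`, delegating to `stats::p.adjust`; an independent textbook
   step-up implementation in the tests checks it bit-for-bit). A feature is
   `up` iff log2FC $> 2$ *and* adjusted $p < 0.05$, both strict;
   `classify_de()` exposes the thresholds so the secondary regime
   (log2FC $> 1$, raw $p < 0.05$) used for drug-metabolizing enzyme panels
   is one argument away. log2FC is computed on pseudocounted (+0.5) group
   means of the scaled counts so it is finite at zeros.

## Alternative-TSS activity and switching

At a locus whose $k$ transcript variants (TVs) share a 3' terminus, TVs are
ordered TV1..TVk from the most upstream TSS in transcription direction, and
each TV owns the **unique segment** between its TSS and the next
(`tss_segments()`; minus-strand loci are handled by coordinate reflection).
Segments tile the locus exactly — a conservation property the tests assert
against whole-locus quantification.

Because nascent coverage accumulates downstream, the segment FPKMs are
cumulative sums of per-TSS initiation rates. Two quantities are derived per
group (`build_tss_profiles()`):

* the adjacent-difference statistic
  $\Delta_i = \mathrm{FPKM}(\mathrm{seg}_i) - \mathrm{FPKM}(\mathrm{seg}_{i+1})$,
  the printed form of "signal difference between adjacent elements", kept
  as the clustering feature vector;
* the **initiation activity** of each TSS, obtained by deconvolving the
  accumulation: $a_1 = \mathrm{FPKM}(\mathrm{seg}_1)$ and
  $a_i = \mathrm{FPKM}(\mathrm{seg}_i) - \mathrm{FPKM}(\mathrm{seg}_{i-1})$
  for $i > 1$. This is the package's own design choice: the raw argmax of
  segment FPKM is structurally biased toward the 3'-most segment (which
  accumulates every upstream TSS), so dominance is defined as the argmax of
  activity instead. The alternative full-nested-span quantification is
  available behind `full_span = TRUE`.

A locus is called **switching** (`detect_tss_switching()`) iff the dominant
TV differs between at least one pair of groups and every group's dominant
activity exceeds 1 FPKM — reusing the expressed-transcript cutoff so
dominance is never decided on near-silent loci. Loci are clustered on their
concatenated per-group $\Delta$ vectors, min-max scaled per locus, with
**uncentered correlation distance**
$d(x,y) = 1 - \sum x_i y_i / (\|x\|\,\|y\|)$ under average linkage (UPGMA,
via `stats::hclust`); an $O(n^3)$ naive implementation in the tests checks
the merge heights. Loci with differing $k$ are compared by padding absent
adjacent differences with zero.

## lncRNA classification

* **Known vs novel**: same-strand overlap of at least 1 bp with any
  reference transcript (`mark_known()`).
* **Bidirectional (divergent) pairs**: two transcripts pair iff they are on
  opposite strands, transcribe away from each other, and their TSSs are at
  most 500 bp apart — the standard divergent-eRNA scale; matching is
  greedy, closest pair first, one partner each (`pair_bidirectional()`).
* **Promoter vs enhancer**: within $\pm 1$ kb of the TSS the covered bases
  of H3K4me3 ($c_3$) and H3K4me1 ($c_1$) peaks are compared: promoter iff
  $c_3 > 0$ and $c_3 \ge c_1$; enhancer iff $c_1 > 0$ and $c_1 > c_3$;
  otherwise unclassified. Ties go to promoter because H3K4me3 is the more
  specific promoter mark. Window and tie rule are package decisions — the
  qualitative "prominent presence" criterion needs an operational form —
  and the window is configurable (`classify_chromatin()`).
* **Super-enhancer overlap**: strand-agnostic 1 bp overlap of the
  transcript span with any SE interval (`flag_super_enhancer()`).

## Guilt by association, GO and hubs

`hypergeom_enrich()` computes, per term, the exact upper-tail
hypergeometric $P[X \ge k]$ for $k$ study hits among $n$ study genes, $K$
carriers among $N$ population genes, plus the enrichment factor
$(k/n)/(K/N)$, BH adjustment across terms and $-\log_2 p$ for display. The
hypergeometric is a package decision (no test is named in the figure
legends); it is the natural one-sided over-representation test on a flat
gene-to-term table, and no GO-graph propagation is attempted.

`correlate_with_nearest_gene()` computes Pearson $r$ on
$\log_2(\mathrm{FPKM}+1)$ across samples between each lncRNA and its
nearest coding gene (signed TSS-to-TSS distance, ties toward the smaller
coordinate then the lexicographically smaller id); Spearman is a flag.
Zero-variance profiles yield `NA` and are excluded from category means.
Categories — novel, promoter, enhancer, SE — may overlap, so summaries are
per-category, not a partition. `transfer_go_to_lncrnas()` builds a study
set per category either from the nearest genes of the members (default) or
from all genes correlated at $|r| \ge 0.7$ with any member, and runs the
enrichment on it. `hub_mirnas()` restricts the interaction table to
expressed miRNAs and calls hubs by a degree threshold; any scoring beyond
degree is out of scope.

## Motifs and TFs

`scan_pwm()` scores every window of a sequence with
$\sum_j \log_2(p_{b_j,j}/q_{b_j})$ against a uniform background on both
strands (the minus strand via the reverse-complemented matrix), skipping
windows with `N`. The default hit threshold is 80% of the PWM's maximum
achievable score — common PWM practice, configurable in bits. The
`motif_enrichment()` statistic is sequence-level: the fraction of sequences
with at least one hit, compared between disjoint target and background TSS
window sets ($\pm 200$ bp, core-promoter scale) with the same exact
hypergeometric tail as the GO test; a hit-count-level percentage is
available behind `count_level = TRUE`. `tf_motif_correlation()` min-max
scales TF expression rows and motif enrichment rows to $[-1,1]$ over the
same ordered condition sets, computes Spearman $\rho$ per mapped TF–motif
pair, and clusters rows and columns with complete linkage on
$1-\rho$ — the stated clustering of the corresponding heatmaps.

## The synthetic study

`sim_config()` defines the simulated experiment; `simulate_bundle()` writes
the complete input bundle (FASTA, BED12, bedGraph pairs, peak BEDs, PWM,
GO/target tables, truth table, YAML manifest) deterministically — identical
configs give byte-identical bundles, which the end-to-end determinism test
relies on.

Defaults, chosen once as a desk-scale caricature of a stem-cell to
hepatocyte comparison: two groups of 4 replicates; 60 coding genes, 40
lncRNAs (30% with a divergent partner 100–400 bp upstream on the other
strand), 12 pri-miRNA loci with 2–4 TSSs sharing a 3' end; baseline
expression 20 FPKM with 1.5-log2-units of spread; 25% of features changed
8-fold (half up, half down); NB dispersion 0.1 — a typical biological CV of
~32%; 64% of lncRNAs enhancer-class; library size $10^6$ with planted
rates renormalized so the expected per-sample read total equals it, the
realized totals being recorded in the manifest. With more than two groups
the planted log2FC is graded linearly across the non-reference groups,
emulating a differentiation gradient. Reads are 1-bp coverage increments
placed uniformly over the feature span — the resolution claim of run-on
data, and it keeps per-base oracles exact; multi-TSS loci place each TV's
reads over its full span so that accumulation holds by construction.

Geometry guarantees make the ground truth recoverable *in principle*:
same-strand loci never overlap; each lncRNA sits 1.85–2.3 kb from a
dedicated neighbour gene that shares its regulation (so nearest-gene
correlation and GO transfer have signal), while peaks of different loci
stay outside each other's $\pm 1$ kb classification windows; divergent
partners share their host's chromatin class and SE interval, as one would
expect of a shared regulatory element. TF genes `TF_<motif>` are forced up
or down to match their motif's planted direction, and motif consensus
strings are written at non-colliding positions within $\pm 200$ bp of the
TSSs of regulated lncRNAs.

What the generator does **not** emulate — and therefore what green tests do
not show about real data: mappability and GC biases, read-length effects,
overlapping or nested genes beyond shared-3'-end TV nests, polymerase
pausing peaks, intron/exon structure (whole spans are transcribed
uniformly), tagwise dispersion variation, batch effects, and peak calls
with false positives (jitter of the peak positions is available via
`peak_jitter`, boundary errors beyond a shift are not modelled).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GTF export converts to
  1-based closed and back losslessly.
* p-values are computed in log space and normalized before tail summation;
  ties compare with a $1+10^{-7}$ relative tolerance.
* Constant rows min-max scale to zero; zero vectors are an error for the
  uncentered distance (it is undefined there), and constant-profile loci
  are dropped from clustering with a warning.
* Empty reference annotations give all-novel; empty SE files give no
  flags; an empty bedGraph is a valid zero track.
* Greedy pairing breaks distance ties by smaller row indices; UPGMA merge
  ties follow `hclust`; nearest-TSS ties break toward the smaller
  coordinate, then the smaller id.
* The generator refuses configurations whose loci cannot be placed,
  naming the approximate base-pair deficit.

## Problem sizes

The test-suite and acceptance experiments run at deliberately modest sizes
chosen as the package's own desk-scale defaults: toy genomes of 0.3–1.6 Mb,
100–150 features, 8–12 samples at $10^6$ reads each, 2,000-feature null
calibrations, 100-locus switch-recovery runs and 80-motif null scans. At
these sizes the full suite and the acceptance script each complete in a few
minutes on one core.

## Limitations

The exact NB test uses one common dispersion; genes with outlying
variability will be anti-conservative. The switching caller compares only
dominant TSSs — partial usage shifts that never change the argmax are
reported in the $\Delta$ vectors but not flagged. Chromatin classification
trusts the input peak sets; no peak calling is performed. The GO machinery
treats the gene-to-term table as flat, ignoring the ontology graph. All
window sizes (TSS $\pm 1$ kb, pairing 500 bp, motif $\pm 200$ bp) are
field-standard defaults, not fitted quantities, and are exposed as
arguments throughout.
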