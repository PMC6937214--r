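---
title: "Methods: integrating H3K4ox ChIP-seq with chromatin state and accessibility"
author: "oxichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating H3K4ox ChIP-seq with chromatin state and accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(oxichrom)
  library(GenomicRanges)
})
```

## The biological question

LOXL2 is an amine oxidase that deaminates the ε-amino group of lysine 4 on
histone H3, producing an oxidized mark (H3K4ox) enriched in triple-negative
breast cancer (TNBC) cells. The analytical question this package addresses
is *where* that mark sits — which chromatin states it occupies, whether it
coincides with lamin-associated domains (LADs) — and *what it does*: how
chromatin accessibility (ATAC-seq) responds at H3K4ox-marked sites when
LOXL2 is knocked down, whether repetitive elements are de-repressed, and
which differentially expressed genes lie near the affected accessible sites.

Every stage is an integration of standard genomic data types: peak sets
(narrowPeak), state segmentations (ChromHMM-style BED), per-base coverage
(bedGraph), a TE family count table, and a differential-gene table. The
package represents intervals as `GRanges` and coverage as `RleList`, the
standard Bioconductor containers, and exposes each analysis stage as plain
functions.

## Nucleotide-level state enrichment

Enrichment of a peak set in a chromatin state category is assessed at
single-base resolution. With an effective genome of $G$ bp, peak set $P$
and category $C$, every base of the effective genome is cross-classified:

$$a = |P \cap C|,\quad b = |P| - a,\quad c = |C| - a,\quad d = G - a - b - c,$$

and the association is tested with Fisher's exact test on
$\begin{pmatrix} a & b \\ c & d \end{pmatrix}$, by default one-sided
("greater", i.e. overrepresentation of peak bases inside the category).
Two useful summaries are reported alongside: the odds ratio $ad/bc$ and the
fold enrichment $\frac{a/(a+b)}{(a+c)/G}$ (fraction of peak bases in the
category over the category's genomic fraction).

Three numerical points deserve note:

* **Merging before counting.** Peaks and categories are reduced to disjoint
  unions first, so duplicated or overlapping records never double-count a
  nucleotide, and the cells always sum to exactly $G$.
* **Effective genome size.** $d$ is computed as the difference from the
  effective (mappable) genome size used for peak calling — for hg19 the
  conventional value is 2,700,000,000 bp; synthetic genomes are fully
  mappable, so $G$ defaults to the summed chromosome lengths. If the
  peak/category union exceeds $G$ the function stops and asks for a larger
  $G$ rather than producing a negative cell.
* **Calibration caveat.** Treating each base pair as an independent trial is
  exactly right only when the placed units are single bases. Real peaks are
  contiguous runs of hundreds of correlated bases, which inflates the
  effective count by roughly the peak length; bp-level p-values on real
  peaks are therefore *anticonservative* and should be read as enrichment
  scores comparable across categories, not calibrated error rates. Our null
  calibration test re-places peaks as independent single bases — the regime
  in which the exact test is calibrated (rejection fraction ≈ 5% at
  p < 0.05) — and the planted-enrichment test demonstrates the intended
  use: ranking categories and detecting a strong planted signal.

One-sidedness is a deliberate default, not a claim about upstream
conventions: overrepresentation is the hypothesis of interest, and the
two-sided minimum-likelihood p-value is available by flag. p-values are
reported raw, one per category, with no multiple-testing correction (each
category is a separate genome-level test; there are seven of them).

The same machinery runs unchanged against a single-category annotation
such as LADs.

The default state grouping collapses the Broad ChromHMM 15-state labels into
seven categories — promoter (states 1+2), poised promoter (3), strong
enhancer (4+5), poised/weak enhancer (6+7), insulator (8), repressed (12),
heterochromatin (13). Label strings differ between ChromHMM releases, so the
grouping is plain data and fully user-overridable.

## ATAC peak classification and summit metaprofiles

Significant ATAC peaks are those with calling p-value strictly below
$10^{-5}$ (peak calling is assumed to have run without an FDR restriction,
leaving this as the single significance gate). Each significant peak is
classified by the fraction of its bases covered by the union of H3K4ox
peaks: strictly more than 95% makes it *overlapping*, anything else
*orphan*. Both thresholds are strict on purpose — a peak at exactly
p = $10^{-5}$ or exactly 95% coverage is excluded/orphan — and the two
labels partition the input by construction.

For signal summaries, replicate coverage tracks are averaged per position,
and each peak contributes a row to a summit-aligned matrix: entry $(i, o)$
is the averaged coverage at $\mathrm{summit}_i + o$ for offsets
$o = -F..F$ at 1-bp resolution. The summit is the narrowPeak summit when
present and the interval midpoint otherwise (peak callers emit summits;
the fallback only matters for degenerate inputs). Offsets falling outside
the chromosome contribute 0 and the row is flagged, keeping the matrix
rectangular.

The *linear metaprofile* sums each matrix column over peaks and divides
both conditions' sums by the **control** sum at offset 0. This pins the
control profile to exactly 1.0 at the summit and expresses every other
value relative to the maximum control signal — so the knockdown/control
ratio at the summit can be read directly off the knockdown profile. The
flank defaults to 2000 bp; the packaged analyses and tests use 300–500 bp,
which fully contains the simulated bump (σ = 150 bp) and keeps matrices
small.

Averaging replicates before or after window extraction is mathematically
irrelevant for means; the implementation averages tracks first.

## Replicate correlation

Per-base coverage tracks of two replicates are aligned by genomic position
after filtering zero-count positions. The filter keeps positions nonzero in
*both* tracks: filtering each replicate and then merging aligned by
position leaves exactly the jointly nonzero set (a `union` mode, imputing
zeros, is available for sensitivity checks). Pearson's correlation is
computed on all retained positions, and additionally on a random
100,000-position subsample — the subsample is what a scatter plot shows,
and on well-behaved tracks the two values agree within sampling error
(our property test bounds the deviation at 0.02 over 50 seeds). The
subsample seed defaults to a fixed value so plots are reproducible.

## TE differential expression with TMM normalization

TE expression arrives as a families × samples count table. Between-sample
normalization uses the trimmed mean of M-values (TMM): for sample $s$
against a reference $r$ with library sizes $N_s, N_r$ and counts
$y_{gs}, y_{gr}$,

$$M_g = \log_2 \frac{y_{gs}/N_s}{y_{gr}/N_r}, \qquad
  A_g = \tfrac12 \log_2 \left( \frac{y_{gs}}{N_s} \cdot \frac{y_{gr}}{N_r} \right),$$

families with a zero count in either sample are dropped, the most extreme
30% by $M$ and 5% by $A$ (two-sided) are trimmed, and the factor is
$2^{\sum w_g M_g / \sum w_g}$ with inverse delta-method variance weights
$w_g^{-1} = \frac{N_s - y_{gs}}{N_s y_{gs}} + \frac{N_r - y_{gr}}{N_r y_{gr}}$.
The reference sample is the one whose 75th-percentile relative abundance is
closest to the across-sample mean, and factors are rescaled to geometric
mean exactly 1. These are the established TMM conventions; our test suite
verifies the implementation against a literal step-by-step oracle and
cross-checks it against the edgeR implementation.

Condition means are computed on counts scaled to a common effective library
size, and the fold change is reported as $\log_2(\mathrm{KD}/\mathrm{control})$
— the orientation is fixed by the published table, where Alu has a higher
knockdown mean and a positive log2FC. For comparisons against published
2-decimal values, rounding is half-away-from-zero (the convention of such
tables), with raw values always retained.

Significance uses the strict rule prob > 0.95, where *prob* is the
probability of differential expression from an external engine, accepted
as a first-class input column. Because that engine is external, the package
also offers a clearly labeled permutation **surrogate**: for every balanced
relabeling of the samples other than the observed one, per-family
|log2 fold changes| are recomputed (with the same normalization factors)
and pooled across families and relabelings; a family's surrogate
probability is the fraction of the pooled null strictly below its observed
|log2FC|. With a 2 vs 2 design there are only four informative relabelings,
hence the pooling — the surrogate ranks families sensibly and recovers
large planted effects, but it is a different statistic and is never
claimed to reproduce any published probability column.

Zero-count families propagate as ±Inf/NaN sentinels, never silently
dropped.

## Gene–peak linking

Differentially expressed genes are linked to (typically
H3K4ox-overlapping, significant) ATAC peaks lying within a distance
threshold, direction-agnostic. The gap is 0 for intersecting intervals and
otherwise the number of bases strictly between nearest ends; the threshold
is inclusive, and both 0.5 Mb and 1 Mb are first-class defaults of the
workflow. Distance is measured to the whole gene span by default; since
anchoring at the TSS is an equally defensible convention, an
`anchor = "tss"` mode (5′ end, strand-aware) is provided. Links are unique
per (gene, peak) pair, and chromosome-mismatched pairs never link.

## What the synthetic data emulates — and what it does not

The generators produce every input the pipeline consumes, on a toy genome
of 3 × 1 Mb chromosomes (fully mappable, so the effective size is the
genome size), with planted structure chosen to be recoverable:

* a block segmentation (2 kb blocks) hitting configured per-state genome
  fractions to within rounding (heterochromatin 10% by default);
* an H3K4ox peak set with 80% of peak nucleotides inside heterochromatin
  blocks — peaks never overlap, so merged counting is exercised without
  being load-bearing;
* ATAC peaks with exact planted classes (overlapping peaks strictly inside
  H3K4ox peaks, covered fraction 1; orphans in peak-free blocks, covered
  fraction 0) and planted calling p-values on both sides of the $10^{-5}$
  gate;
* Poisson coverage with Gaussian summit bumps (amplitude 80 reads over a
  background of 2, σ = 150 bp) whose knockdown amplitude is 1.8× at
  overlapping peaks only; replicates are independent draws sharing means,
  which makes the zero-filtered replicate Pearson exceed 0.9 by
  construction. Note the recoverable summit ratio is
  $(2 + 1.8 \cdot 80)/(2 + 80) \approx 1.78$, not exactly 1.8, because the
  background is not scaled — the recovery test's 10% tolerance covers
  this;
* negative-binomial TE counts (dispersion 0.01, per-sample depth
  multipliers) with planted log2 fold changes of +1 and −1;
* genes placed at exact gaps (0, 0.4, 0.9, 1.5 Mb) from chosen overlapping
  peaks. The 1.5 Mb negative control cannot fit on a 1 Mb chromosome; the
  generator warns and skips it there, and the linking analysis uses 4 Mb
  chromosomes.

Each generator draws from its own RNG stream derived from the master seed,
so identical configs give byte-identical files and adding a generator
never perturbs another's output.

What passing these tests does *not* show: real ChIP/ATAC data have
GC- and mappability-structured backgrounds, correlated replicate artifacts,
peak-length and state-segment length distributions far from uniform, and
TE families spanning seven orders of magnitude of abundance. The synthetic
recovery results validate the *computations*, not the biology; the
published-table regressions (log2FC reproduction and the significance
scan) are the package's contact points with real data, and analyses of the
original sequencing data require the deposited accession.

## Numerical choices and degenerate inputs

* Coordinates: files are 0-based half-open (BED convention, explicit
  dialects, no auto-detection); in-memory `GRanges` are 1-based closed, and
  readers/writers convert exactly, so round trips are bit-exact.
* Bookended intervals merge; strand is parsed but ignored throughout.
* Chromosome-name style mismatches ("chr1" vs "1") raise an error, with
  `normalize_chroms()` as the explicit fix.
* Degenerate contingency margins report p = 1 with a flag; two-sided
  enumeration uses the minimum-likelihood rule with a $(1+10^{-7})$
  tolerance on ties (matching the standard implementation) and falls back
  to tail doubling, flagged, for supports above 5 × 10⁶.
* The control metaprofile denominator (control summit column sum) equal to
  0 is an error, not an NaN.
* Pearson correlation on fewer than 2 positions or zero-variance vectors
  is an error, not NA.
* Subsampling and permutation functions restore the caller's RNG state.

## Problem sizes used in the packaged checks

All packaged analyses and tests run on the 3 × 1 Mb default genome (or
4 Mb chromosomes where the 1.5 Mb gene gap is needed); recovery medians use
10–25 seed replicates, null calibration uses 200 seeds of 2,000 re-placed
single bases, and the exact-test oracle sweep enumerates every
hypergeometric configuration with all margins ≤ 60. These sizes were chosen
so that each check isolates one property at comfortable statistical
resolution while the whole suite stays quick to run.

## Known limitations

* The bp-level exact test's anticonservativeness on contiguous peaks is
  inherent to the method (see above); no shuffle-based empirical null is
  provided.
* The permutation probability surrogate has coarse resolution in 2 vs 2
  designs and is pooled across families; it is a stand-in statistic, not a
  reimplementation of the external engine.
* bigWig tracks, BAM input, peak calling and liftover are out of scope;
  coverage enters as bedGraph only.
* Heatmap/row-clustering display utilities are not provided; matrices are
  returned for the user's plotting tool of choice.
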