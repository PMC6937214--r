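# oxichrom

Integrative chromatin analysis of the oxidized histone mark **H3K4ox**
(deposited by the amine oxidase LOXL2) in triple-negative breast cancer:
where the mark sits in the genome, and what happens to chromatin
accessibility, repetitive-element expression and nearby gene expression
when LOXL2 is knocked down.

The package implements six analysis stages as plain R functions over
Bioconductor containers (`GRanges`, `RleList`), plus seeded synthetic-data
generators that plant recoverable structure in every input, so the whole
workflow runs and is tested without any external download:

| Stage | Core function(s) | What it computes |
|---|---|---|
| State enrichment | `build_contingency()`, `fisher_enrichment()`, `enrich_all()` | Nucleotide-level 2×2 table of peak vs chromatin-state bases over the effective genome size G; Fisher exact test, odds ratio, fold enrichment |
| ATAC classification | `filter_significant()`, `classify_peaks()` | Significant ATAC peaks (p < 1e-5, strict) labeled *overlapping* (> 95% of the peak covered by H3K4ox peaks, strict) or *orphan* |
| Summit metaprofiles | `summit_matrix()`, `linear_profile()` | Summit-aligned per-base signal matrices; position-wise sums normalized to the control summit (control = 1.0 at offset 0) |
| Replicate correlation | `pair_and_filter()`, `replicate_correlation()` | Pearson r of per-base coverage on jointly nonzero positions, full and 100k-position subsample |
| TE differential expression | `tmm_factors()`, `te_diffexp()` | TMM normalization, condition means, log2(KD/control), strict prob > 0.95 significance |
| Gene–peak linking | `link_genes()` | Differential genes within 0.5 / 1 Mb (inclusive, direction-agnostic) of overlapping ATAC peaks |

The enrichment statistic is Fisher's exact test on the nucleotide-level
contingency table

```
            in category   not in category
in peaks         a               b            a = |P ∩ C|
not in peaks     c               d            a+b+c+d = G_eff
```

with fold enrichment `(a/(a+b)) / ((a+c)/G)`. TMM follows the standard
trimmed-mean-of-M-values conventions (trim 0.30 on M, 0.05 on A,
inverse-variance weights, 75th-percentile reference, geometric mean 1); the
test suite checks it against a step-by-step oracle and against edgeR.
See `vignettes/oxichrom-methods.Rmd` for the full model description,
parameter meanings, numerical choices and limitations.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic inputs -> results/sim/
Rscript analysis/02_state_enrichment.R
Rscript analysis/03_atac_classes_profiles.R
Rscript analysis/04_replicate_correlation.R
Rscript analysis/05_te_diffexp.R
Rscript analysis/06_gene_linking.R
```

Stage 2 ranks chromatin-state categories by overrepresentation of H3K4ox
peak nucleotides. On the default synthetic genome (3 × 1 Mb; 80% of peak bp
planted in heterochromatin, which occupies 10% of the genome) it prints:

```
Top-ranked category: heterochromatin (fold enrichment 8.00, one-sided p 0)
```

— the planted 80%/10% structure appears as a fold enrichment of 8, with a
p-value that underflows to 0; all other categories are at fold ≤ 0.6, p = 1.

Stage 3 classifies the 100 significant ATAC peaks and builds
control-summit-normalized metaprofiles:

```
100 of 120 ATAC peaks significant; 40 overlapping, 60 orphan
overlapping  summit: control 1.000, KD 1.768 (KD/control 1.77)
orphan       summit: control 1.000, KD 0.999 (KD/control 1.00)
```

The control profile is pinned to exactly 1.0 at the summit by construction;
the knockdown gain appears only at H3K4ox-overlapping peaks and recovers
the planted 1.8× amplitude (the observed 1.77 reflects the unscaled
2-read background under an 80-read bump).

Stage 5 re-derives the published TE log2 fold changes from the published
condition means and applies the strict significance rule:

```
 family log2fc log2fc_recomputed prob significant
    Alu   0.04              0.04 1.00        TRUE
    RNA   0.06              0.06 0.99        TRUE
   ERVK   0.08              0.08 0.76       FALSE
significant families (prob > 0.95): Alu, RNA, L1
```

and on the synthetic table recovers the planted ±1 log2 fold changes
(estimates 0.91 and −1.00, both flagged significant by the permutation
surrogate). Stage 6 links genes planted at 0 / 0.4 / 0.9 / 1.5 Mb from
overlapping peaks: the first two link at 0.5 Mb, the first three at 1 Mb,
and the 1.5 Mb negative control never links.

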