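#!/usr/bin/env Rscript
# Stage 1: generate one full set of synthetic inputs under the default
# study conditions (3 x 1 Mb genome, 80% of H3K4ox peak bp planted in
# heterochromatin, 40/60 overlapping/orphan ATAC peaks, 1.8x knockdown
# accessibility gain, planted TE fold changes) and write them under
# results/sim/ for the later stages.

suppressPackageStartupMessages(library(oxichrom))

seed <- 20190828
cfg <- sim_config(seed = seed)
print(cfg)

outdir <- "results/sim"
files <- suppressWarnings(write_sim_fixtures(cfg, outdir))
# (the 1.5 Mb gene gap cannot fit on a 1 Mb chromosome and is skipped; the
# gene-linking stage regenerates genes on a larger genome)

cat("wrote", length(files), "files to", outdir, ":\n")
cat(paste(" -", basename(files)), sep = "\n")
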