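suppressPackageStartupMessages(library(GenomicRanges))

test_that("generators are pure functions of the config: byte-identical files", {
  cfg <- sim_config(seed = 42)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  suppressWarnings({   # 1.5 Mb gene gap cannot fit on a 1 Mb chromosome
    f1 <- write_sim_fixtures(cfg, d1)
    f2 <- write_sim_fixtures(cfg, d2)
  })
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), info = nm)
  # a different seed changes the output
  suppressWarnings(f3 <- write_sim_fixtures(sim_config(seed = 43),
                                            file.path(tempdir(), "simC")))
  expect_false(identical(readLines(f1[["h3k4ox"]]),
                         readLines(f3[["h3k4ox"]])))
})

test_that("generated files re-parse through the readers with no errors", {
  cfg <- sim_config(seed = 11)
  d <- file.path(tempdir(), "simParse")
  suppressWarnings(f <- write_sim_fixtures(cfg, d))
  seg <- read_bed(f[["segmentation"]], "segmentation")
  chip <- read_bed(f[["h3k4ox"]], "narrowPeak")
  atac <- read_bed(f[["atac"]], "narrowPeak")
  expect_equal(length(chip), cfg$n_chip_peaks)
  expect_equal(length(atac), cfg$n_atac_overlapping + cfg$n_atac_orphan +
               cfg$n_atac_nonsig)
  expect_true(all(!is.na(mcols(atac)$pvalue)))
  expect_true(all(!is.na(mcols(atac)$summit)))
  genome <- oxi_genome(setNames(rep(cfg$chrom_len, cfg$n_chroms),
                                paste0("chr", 1:cfg$n_chroms)))
  tr <- read_bedgraph(f[["ctrl1"]], genome)
  expect_equal(unname(lengths(tr)), rep(cfg$chrom_len, cfg$n_chroms))
  cnt <- read_te_counts(f[["te_counts"]])
  expect_equal(dim(cnt), c(cfg$te_n_families, 4))
  genes <- read_gene_table(f[["genes"]])
  expect_gte(length(genes), 2)   # large gaps cannot fit on 1 Mb chromosomes
})

test_that("segmentation fractions land within 2% of the configured ones", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s)
    sim <- simulate_segmentation(cfg)
    G <- sum(sim$genome$chrom_sizes)
    for (st in names(cfg$state_fractions)) {
      realized <- total_nt(sim$segmentation[
        mcols(sim$segmentation)$state == st]) / G
      expect_lt(abs(realized - cfg$state_fractions[[st]]), 0.02)
    }
  }
  # one state at fraction ~1 labels the whole genome
  cfg1 <- sim_config(seed = 1, state_fractions = c(het = 1.0),
                     target_state = "het")
  sim1 <- simulate_segmentation(cfg1)
  expect_equal(total_nt(sim1$segmentation), sum(sim1$genome$chrom_sizes))
})

test_that("peak generator plants the target-state fraction and exact classes", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s)
    sim <- simulate_segmentation(cfg)
    pk <- simulate_peaks(cfg, sim$segmentation)
    het <- sim$segmentation[
      mcols(sim$segmentation)$state == cfg$target_state]
    frac <- total_nt(gi_intersect(pk$chip_peaks, het)) /
      total_nt(pk$chip_peaks)
    expect_lt(abs(frac - cfg$planted_state_frac), 0.03)
    # planted overlap structure: overlapping peaks fully covered, orphans at 0
    cl <- classify_peaks(filter_significant(pk$atac_peaks), pk$chip_peaks)
    expect_identical(as.character(mcols(cl)$label),
                     mcols(cl)$true_label)
    expect_true(all(mcols(cl)$covered_fraction[
      mcols(cl)$label == "overlapping"] >= 0.96))
    expect_true(all(mcols(cl)$covered_fraction[
      mcols(cl)$label == "orphan"] < 0.90))
    # significance filter retains exactly the planted significant count
    expect_equal(length(cl), cfg$n_atac_overlapping + cfg$n_atac_orphan)
  }
})

test_that("TE table generator encodes the planted fold changes", {
  cfg0 <- sim_config(seed = 2, te_planted_lfc = setNames(numeric(0), NULL))
  te0 <- simulate_te_table(cfg0)
  res0 <- te_diffexp(te0$counts, te0$condition)
  expect_lt(abs(median(res0$log2fc)), 0.1)   # null table: median near 0
  ests <- vapply(1:20, function(s) {
    te <- simulate_te_table(sim_config(seed = s))
    te_diffexp(te$counts, te$condition)$log2fc[1:2]
  }, numeric(2))
  expect_lt(abs(median(ests[1, ]) - 1), 0.1)
  expect_lt(abs(median(ests[2, ]) + 1), 0.1)
  # determinism
  expect_identical(simulate_te_table(sim_config(seed = 9))$counts,
                   simulate_te_table(sim_config(seed = 9))$counts)
})

test_that("gene generator places genes at the configured gaps", {
  cfg <- sim_config(seed = 3, chrom_len = 4e6,
                    gene_gaps = c(0, 4e5, 9e5, 1.5e6))
  sim <- simulate_segmentation(cfg)
  pk <- simulate_peaks(cfg, sim$segmentation)
  genes <- simulate_genes(cfg, pk$atac_peaks)
  expect_equal(length(genes), 4)
  over <- pk$atac_peaks[mcols(pk$atac_peaks)$true_label == "overlapping"]
  for (i in seq_along(genes)) {
    anchor <- over[mcols(over)$name == mcols(genes)$anchor_peak[i]]
    d <- GenomicRanges::distance(genes[i], anchor)
    expected <- mcols(genes)$planted_gap[i]
    expect_equal(d, if (expected == 0) 0 else expected)
  }
  # gap 0.4 Mb links at 0.5 Mb; gap 1.5 Mb never links at shipped thresholds
  l5 <- link_genes(genes, over, 5e5)
  expect_true("gene_gap_400000" %in% l5$gene_id)
  expect_false(any(l5$gene_id == "gene_gap_1500000" &
                   l5$peak == mcols(genes)$anchor_peak[
                     mcols(genes)$gene_id == "gene_gap_1500000"]))
  l10 <- link_genes(genes, over, 1e6)
  anchor_links <- merge(l10,
                        data.frame(gene_id = mcols(genes)$gene_id,
                                   peak = mcols(genes)$anchor_peak,
                                   gap = mcols(genes)$planted_gap))
  expect_setequal(anchor_links$gap[anchor_links$distance ==
                                   anchor_links$gap], c(0, 4e5, 9e5))
})

test_that("coverage generator: fold 1.0 gives flat KD/control ratio", {
  cfg <- sim_config(seed = 4, kd_fold = 1.0)
  sim <- simulate_segmentation(cfg)
  pk <- simulate_peaks(cfg, sim$segmentation)
  cov <- simulate_coverage(cfg, pk$atac_peaks)
  cl <- classify_peaks(filter_significant(pk$atac_peaks), pk$chip_peaks)
  over <- cl[mcols(cl)$label == "overlapping"]
  ctrl <- average_tracks(list(cov$ctrl1, cov$ctrl2))
  kd <- average_tracks(list(cov$kd1, cov$kd2))
  pr <- linear_profile(summit_matrix(over, kd, 300),
                       summit_matrix(over, ctrl, 300))
  ratio <- pr$kd[pr$offset == 0] / pr$ctrl[pr$offset == 0]
  expect_lt(abs(ratio - 1), 0.1)
  # determinism of the track draw
  cov2 <- simulate_coverage(cfg, pk$atac_peaks)
  expect_identical(cov$ctrl1, cov2$ctrl1)
})
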