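#' Configuration for the synthetic-data generators
#'
#' One serializable object holds every knob of the generators; each
#' generator is a pure function of it (plus its own derived RNG stream), so
#' identical configs give byte-identical outputs and adding a generator
#' never perturbs the others.
#'
#' Defaults describe a fully mappable toy genome of 3 chromosomes x 1 Mb on
#' which every analysis stage runs in seconds while keeping the statistical
#' structure of the real inputs: a 7-category chromatin segmentation with
#' 10% heterochromatin; an H3K4ox peak set with 80% of its nucleotides
#' planted in heterochromatin; ATAC peaks split into known overlapping /
#' orphan classes with planted significance p-values; summit-shaped ATAC
#' coverage with a 1.8x knockdown gain at H3K4ox-overlapping peaks;
#' negative-binomial TE family counts with planted log2 fold changes; and
#' genes placed at fixed gaps from chosen overlapping peaks.
#'
#' @param seed Master integer seed; per-generator streams derive from it.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param block_len Segmentation block size in bp.
#' @param state_fractions Named genome fractions per state (sum <= 1; the
#'   remainder is unlabeled).
#' @param target_state State in which H3K4ox peak nucleotides are planted.
#' @param n_chip_peaks Number of H3K4ox peaks.
#' @param chip_peak_len Length range (min, max) of H3K4ox peaks, bp.
#' @param planted_state_frac Fraction of H3K4ox peak bp inside
#'   `target_state`.
#' @param n_atac_overlapping,n_atac_orphan Significant ATAC peaks fully
#'   inside / fully outside H3K4ox peaks.
#' @param n_atac_nonsig Additional ATAC peaks that fail the significance
#'   filter.
#' @param atac_sig_p,atac_nonsig_p Planted peak-calling p-values.
#' @param background_rate Poisson background coverage per base.
#' @param summit_amplitude Gaussian bump height at ATAC summits (reads).
#' @param summit_sigma Bump standard deviation, bp.
#' @param kd_fold Knockdown/control amplitude ratio at overlapping peaks.
#' @param te_n_families Number of TE families.
#' @param te_baseline_range Range of baseline mean counts (log-uniform).
#' @param te_planted_lfc Named vector of planted log2 fold changes (family
#'   names `FAM01`, `FAM02`, ... ; unnamed families are null).
#' @param te_dispersion Negative-binomial dispersion.
#' @param te_depth_factors Per-sample sequencing-depth multipliers
#'   (control1, control2, kd1, kd2).
#' @param gene_gaps Gaps (bp) at which genes are placed from chosen
#'   overlapping ATAC peaks.
#' @param gene_len Gene length, bp.
#' @param effective_size Effective genome size; defaults to the full toy
#'   genome (fully mappable).
#' @return Object of class `oxi_sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 3, chrom_len = 1e6, block_len = 2000,
                       state_fractions = c(promoter = 0.03,
                                           poised_promoter = 0.01,
                                           strong_enhancer = 0.03,
                                           poised_weak_enhancer = 0.04,
                                           insulator = 0.02,
                                           repressed = 0.07,
                                           heterochromatin = 0.10),
                       target_state = "heterochromatin",
                       n_chip_peaks = 150, chip_peak_len = c(500, 1500),
                       planted_state_frac = 0.8,
                       n_atac_overlapping = 40, n_atac_orphan = 60,
                       n_atac_nonsig = 20,
                       atac_sig_p = 1e-8, atac_nonsig_p = 1e-3,
                       background_rate = 2, summit_amplitude = 80,
                       summit_sigma = 150, kd_fold = 1.8,
                       te_n_families = 20,
                       te_baseline_range = c(100, 1e5),
                       te_planted_lfc = c(FAM01 = 1, FAM02 = -1),
                       te_dispersion = 0.01,
                       te_depth_factors = c(1, 1.1, 0.9, 1.05),
                       gene_gaps = c(0, 4e5, 9e5, 1.5e6),
                       gene_len = 20000,
                       effective_size = n_chroms * chrom_len) {
  cfg <- as.list(environment())
  if (sum(state_fractions) > 1)
    stop("state fractions sum above 1")
  if (any(state_fractions < 0) || any(state_fractions > 1))
    stop("state fractions must lie in [0, 1]")
  if (!target_state %in% names(state_fractions))
    stop("target_state absent from state_fractions")
  if (planted_state_frac < 0 || planted_state_frac > 1)
    stop("planted_state_frac must lie in [0, 1]")
  if (chip_peak_len[2] > block_len)
    stop("chip peaks must fit inside one segmentation block")
  if (length(te_depth_factors) != 4)
    stop("te_depth_factors must have 4 entries (control1, control2, kd1, kd2)")
  structure(cfg, class = "oxi_sim_config")
}

#' @export
print.oxi_sim_config <- function(x, ...) {
  cat("<oxi_sim_config> seed ", x$seed, ", ", x$n_chroms, " x ",
      format(x$chrom_len, scientific = FALSE), " bp, ",
      x$n_chip_peaks, " H3K4ox peaks (", 100 * x$planted_state_frac,
      "% bp in ", x$target_state, "), kd_fold ", x$kd_fold, "\n", sep = "")
  invisible(x)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Simulate a chromatin-state segmentation
#'
#' Tiles each chromosome into `block_len`-bp blocks and assigns
#' `round(fraction * n_blocks)` randomly placed blocks to each state, so the
#' realized per-state genome fraction matches the configured one up to
#' rounding. Unassigned blocks stay unlabeled (no record emitted).
#'
#' @param cfg A [sim_config()].
#' @return List with `segmentation` (a `GRanges` with `state`) and `genome`
#'   (an [oxi_genome()]).
#' @export
simulate_segmentation <- function(cfg) {
  stopifnot(inherits(cfg, "oxi_sim_config"))
  chroms <- sim_chrom_names(cfg)
  n_blocks <- floor(cfg$chrom_len / cfg$block_len)
  per_state <- round(cfg$state_fractions * n_blocks)
  if (sum(per_state) > n_blocks) stop("state fractions infeasible at this block size")
  segs <- with_seed(stream_seed(cfg$seed, 1), lapply(chroms, function(ch) {
    lab <- rep(NA_character_, n_blocks)
    free <- seq_len(n_blocks)
    for (st in names(per_state)) {
      take <- sample(free, per_state[[st]])
      lab[take] <- st
      free <- setdiff(free, take)
    }
    keep <- which(!is.na(lab))
    GRanges(ch, IRanges((keep - 1) * cfg$block_len + 1,
                        keep * cfg$block_len),
            state = lab[keep])
  }))
  seg <- sort(suppressWarnings(do.call(c, segs)))  # per-chrom seqlevel merge
  genome <- oxi_genome(setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms),
                       cfg$effective_size)
  list(segmentation = seg, genome = genome)
}

# place n intervals of the given lengths, each inside a distinct block
place_in_blocks <- function(blocks, lens) {
  stopifnot(length(blocks) >= length(lens))
  idx <- sample(seq_along(blocks), length(lens))
  b <- blocks[idx]
  off <- floor(runif(length(lens)) * (width(b) - lens + 1))
  GRanges(seqnames(b), IRanges(start(b) + off, width = lens))
}

#' Simulate H3K4ox and ATAC peak sets
#'
#' H3K4ox peaks: `planted_state_frac` of the peaks (hence, up to peak-length
#' noise, of peak nucleotides) sit fully inside `target_state` blocks, the
#' rest fully inside blocks of other states or unlabeled genome; peaks never
#' overlap each other. ATAC peaks: `n_atac_overlapping` lie strictly inside
#' an H3K4ox peak (covered fraction 1), `n_atac_orphan` in peak-free blocks
#' (covered fraction 0), both with planted p-value `atac_sig_p`;
#' `n_atac_nonsig` additional orphan-placed peaks get `atac_nonsig_p` and
#' fail the default significance filter. All ATAC peaks carry midpoint
#' summits.
#'
#' @param cfg A [sim_config()].
#' @param seg Segmentation from [simulate_segmentation()] (the `GRanges`).
#' @return List with `chip_peaks` and `atac_peaks` (`GRanges`; ATAC carries
#'   `name`, `pvalue`, `summit`, `true_label`).
#' @export
simulate_peaks <- function(cfg, seg) {
  stopifnot(inherits(cfg, "oxi_sim_config"))
  with_seed(stream_seed(cfg$seed, 2), {
    target_blocks <- seg[mcols(seg)$state == cfg$target_state]
    other_blocks <- seg[mcols(seg)$state != cfg$target_state]
    # unlabeled blocks, recovered from the gaps between labeled ones
    chroms <- sim_chrom_names(cfg)
    genome_gr <- GRanges(chroms, IRanges(1, cfg$chrom_len))
    unlab <- GenomicRanges::setdiff(genome_gr, gi_merge(seg),
                                    ignore.strand = TRUE)
    n_blocks <- floor(width(unlab) / cfg$block_len)
    unlab_blocks <- unlab[n_blocks > 0]
    unlab_blocks <- GRanges(seqnames(unlab_blocks),
                            IRanges(start(unlab_blocks),
                                    width = cfg$block_len))
    off_blocks <- c(granges(other_blocks), unlab_blocks)

    n_in <- round(cfg$planted_state_frac * cfg$n_chip_peaks)
    n_out <- cfg$n_chip_peaks - n_in
    lens <- function(n) floor(runif(n, cfg$chip_peak_len[1],
                                    cfg$chip_peak_len[2] + 1))
    chip <- c(place_in_blocks(target_blocks, lens(n_in)),
              place_in_blocks(off_blocks, lens(n_out)))
    chip <- sort(chip)
    mcols(chip)$name <- sprintf("h3k4ox_%03d", seq_along(chip))
    mcols(chip)$score <- round(runif(length(chip), 50, 500), 2)
    mcols(chip)$in_target <- overlapsAny(chip, target_blocks)

    # overlapping ATAC peaks: strictly inside H3K4ox peaks wide enough to
    # leave a 1-bp margin each side
    wide <- chip[width(chip) >= 200]
    host <- wide[sample(seq_along(wide), cfg$n_atac_overlapping)]
    alen <- pmin(width(host) - 2, 150 + floor(runif(length(host), 0, 50)))
    aoff <- 1 + floor(runif(length(host)) * (width(host) - alen - 1))
    atac_over <- GRanges(seqnames(host), IRanges(start(host) + aoff,
                                                 width = alen))
    # orphan + non-significant peaks: in blocks free of H3K4ox peaks
    free_blocks <- off_blocks[!overlapsAny(off_blocks, chip)]
    atac_orph <- place_in_blocks(free_blocks,
                                 150 + floor(runif(cfg$n_atac_orphan +
                                                   cfg$n_atac_nonsig, 0, 50)))
    atac <- c(atac_over, atac_orph)
    mcols(atac)$name <- sprintf("atac_%03d", seq_along(atac))
    mcols(atac)$pvalue <- c(rep(cfg$atac_sig_p,
                                cfg$n_atac_overlapping + cfg$n_atac_orphan),
                            rep(cfg$atac_nonsig_p, cfg$n_atac_nonsig))
    mcols(atac)$summit <- floor((start(atac) + end(atac)) / 2)
    mcols(atac)$true_label <- c(rep("overlapping", cfg$n_atac_overlapping),
                                rep("orphan", cfg$n_atac_orphan),
                                rep("nonsig", cfg$n_atac_nonsig))
    list(chip_peaks = chip, atac_peaks = atac)
  })
}

#' Simulate replicate ATAC coverage tracks
#'
#' Per-base Poisson counts around a deterministic mean: a flat background of
#' `background_rate` plus, at every significant ATAC peak, a Gaussian bump
#' of height `summit_amplitude` (standard deviation `summit_sigma`) centered
#' on the summit. In the knockdown condition the bump at
#' H3K4ox-overlapping peaks is `kd_fold` times higher; orphan-peak bumps are
#' unchanged. The two replicates per condition are independent Poisson draws
#' from the same mean.
#'
#' @param cfg A [sim_config()].
#' @param atac_peaks ATAC peaks from [simulate_peaks()] (uses `summit` and
#'   `true_label`).
#' @return Named list of `RleList` tracks: `ctrl1`, `ctrl2`, `kd1`, `kd2`.
#' @export
simulate_coverage <- function(cfg, atac_peaks) {
  stopifnot(inherits(cfg, "oxi_sim_config"))
  chroms <- sim_chrom_names(cfg)
  sig <- atac_peaks[mcols(atac_peaks)$true_label != "nonsig"]
  bump_at <- function(mu, summits, amps) {
    halfw <- ceiling(4 * cfg$summit_sigma)
    for (i in seq_along(summits)) {
      lo <- max(1, summits[i] - halfw)
      hi <- min(length(mu), summits[i] + halfw)
      x <- lo:hi
      mu[x] <- mu[x] + amps[i] *
        exp(-((x - summits[i])^2) / (2 * cfg$summit_sigma^2))
    }
    mu
  }
  mus <- lapply(c(ctrl = 1, kd = 2), function(cond) {
    per_chrom <- lapply(chroms, function(ch) {
      mu <- rep(cfg$background_rate, cfg$chrom_len)
      sel <- sig[as.character(seqnames(sig)) == ch]
      if (!length(sel)) return(mu)
      amps <- rep(cfg$summit_amplitude, length(sel))
      if (cond == 2)
        amps[mcols(sel)$true_label == "overlapping"] <-
          cfg$summit_amplitude * cfg$kd_fold
      bump_at(mu, mcols(sel)$summit, amps)
    })
    names(per_chrom) <- chroms
    per_chrom
  })
  with_seed(stream_seed(cfg$seed, 3), {
    draw <- function(mu_list)
      methods::as(lapply(mu_list, function(mu) Rle(rpois(length(mu), mu))),
                  "SimpleRleList")
    list(ctrl1 = draw(mus$ctrl), ctrl2 = draw(mus$ctrl),
         kd1 = draw(mus$kd), kd2 = draw(mus$kd))
  })
}

#' Simulate a TE family count table
#'
#' Negative-binomial counts for `te_n_families` families across two control
#' and two knockdown samples. Family baselines are log-uniform over
#' `te_baseline_range`; families named in `te_planted_lfc` have their
#' knockdown mean multiplied by `2^lfc`; per-sample depth multipliers make
#' TMM normalization non-trivial.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (matrix, samples `ctrl1 ctrl2 kd1 kd2`),
#'   `condition` (`control`/`kd` per sample) and `truth` (named planted
#'   log2 fold change per family, 0 for null families).
#' @export
simulate_te_table <- function(cfg) {
  stopifnot(inherits(cfg, "oxi_sim_config"))
  fams <- sprintf("FAM%02d", seq_len(cfg$te_n_families))
  truth <- setNames(rep(0, cfg$te_n_families), fams)
  planted <- cfg$te_planted_lfc
  unknown <- setdiff(names(planted), fams)
  if (length(unknown))
    stop("planted lfc for unknown families: ", paste(unknown, collapse = ", "))
  truth[names(planted)] <- planted
  with_seed(stream_seed(cfg$seed, 4), {
    base <- exp(runif(cfg$te_n_families, log(cfg$te_baseline_range[1]),
                      log(cfg$te_baseline_range[2])))
    mu <- cbind(base, base, base * 2^truth, base * 2^truth)
    mu <- sweep(mu, 2, cfg$te_depth_factors, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$te_dispersion),
                     nrow = cfg$te_n_families,
                     dimnames = list(fams, c("ctrl1", "ctrl2", "kd1", "kd2")))
    list(counts = counts,
         condition = c("control", "control", "kd", "kd"),
         truth = truth)
  })
}

#' Simulate a differential-gene table near ATAC peaks
#'
#' For each configured gap, places one gene per chosen H3K4ox-overlapping
#' ATAC peak at exactly that many bp downstream of the peak end (upstream of
#' the peak start when it does not fit, skipped with a warning when neither
#' fits). Gap 0 genes overlap their peak. The planted gap is recorded, so
#' [link_genes()] has exact expected output.
#'
#' @param cfg A [sim_config()].
#' @param atac_peaks ATAC peaks from [simulate_peaks()].
#' @return `GRanges` with `gene_id`, `logfc`, `fdr`, `planted_gap`,
#'   `anchor_peak`.
#' @export
simulate_genes <- function(cfg, atac_peaks) {
  stopifnot(inherits(cfg, "oxi_sim_config"))
  over <- atac_peaks[mcols(atac_peaks)$true_label == "overlapping"]
  with_seed(stream_seed(cfg$seed, 5), {
    anchors <- over[sample(seq_along(over), min(length(over),
                                                length(cfg$gene_gaps)))]
    rows <- list()
    for (i in seq_along(cfg$gene_gaps)) {
      gap <- cfg$gene_gaps[i]
      pk <- anchors[((i - 1) %% length(anchors)) + 1]
      s_down <- end(pk) + gap + 1
      s_up <- start(pk) - gap - cfg$gene_len
      if (s_down + cfg$gene_len - 1 <= cfg$chrom_len) s <- s_down
      else if (s_up >= 1) s <- s_up
      else {
        warning("gap ", gap, " bp does not fit on chromosome ",
                seqnames(pk), "; gene skipped")
        next
      }
      g <- GRanges(seqnames(pk), IRanges(s, width = cfg$gene_len))
      mcols(g)$gene_id <- sprintf("gene_gap_%d", gap)
      mcols(g)$logfc <- round(runif(1, -3, 3), 2)
      mcols(g)$fdr <- round(runif(1, 0, 0.05), 4)
      mcols(g)$planted_gap <- gap
      mcols(g)$anchor_peak <- mcols(pk)$name
      rows[[length(rows) + 1]] <- g
    }
    if (!length(rows)) return(GRanges())
    do.call(c, rows)
  })
}

#' Write all synthetic fixtures to a directory
#'
#' Materializes one full set of pipeline inputs: `segmentation.bed`,
#' `h3k4ox.narrowPeak`, `atac.narrowPeak`, four bedGraph coverage tracks,
#' `te_counts.tsv`, `te_truth.tsv` and `genes.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_fixtures <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seg <- simulate_segmentation(cfg)
  pk <- simulate_peaks(cfg, seg$segmentation)
  cov <- simulate_coverage(cfg, pk$atac_peaks)
  te <- simulate_te_table(cfg)
  genes <- simulate_genes(cfg, pk$atac_peaks)
  p <- function(f) file.path(outdir, f)
  write_bed(seg$segmentation, p("segmentation.bed"), "segmentation")
  write_bed(pk$chip_peaks, p("h3k4ox.narrowPeak"), "narrowPeak")
  write_bed(pk$atac_peaks, p("atac.narrowPeak"), "narrowPeak")
  for (nm in names(cov)) write_bedgraph(cov[[nm]], p(paste0(nm, ".bedGraph")))
  write.table(data.frame(family = rownames(te$counts), te$counts,
                         check.names = FALSE),
              p("te_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(family = names(te$truth), true_log2fc = te$truth),
              p("te_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(gene_id = mcols(genes)$gene_id,
                    chrom = as.character(seqnames(genes)),
                    start = start(genes) - 1, end = end(genes),
                    logfc = mcols(genes)$logfc, fdr = mcols(genes)$fdr)
  write.table(gdf, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(segmentation = p("segmentation.bed"),
             h3k4ox = p("h3k4ox.narrowPeak"),
             atac = p("atac.narrowPeak"),
             setNames(p(paste0(names(cov), ".bedGraph")), names(cov)),
             te_counts = p("te_counts.tsv"), te_truth = p("te_truth.tsv"),
             genes = p("genes.tsv"))
  invisible(files)
}
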