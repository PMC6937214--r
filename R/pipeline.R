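#' Run the full analysis pipeline on synthetic data
#'
#' Generates every input from a [sim_config()] and runs all six analysis
#' stages in order: chromatin-state enrichment of the H3K4ox peaks,
#' significance filtering and H3K4ox-overlap classification of the ATAC
#' peaks, summit-aligned metaprofiles of averaged replicate coverage,
#' replicate correlation, TE differential expression with the permutation
#' probability surrogate, and gene-peak linking at both distance thresholds.
#' Returns one structured list with all stage outputs plus the parameters
#' and seed, so two runs from the same config are identical.
#'
#' @param cfg A [sim_config()].
#' @param alpha ATAC significance threshold (default 1e-5).
#' @param min_frac Overlap-classification threshold (default 0.95).
#' @param prob_threshold TE significance threshold (default 0.95).
#' @param distances Gene-linking thresholds in bp (default 0.5 and 1 Mb).
#' @param flank Metaprofile half-window in bp (default 2000).
#' @return Named list: `params`, `enrichment`, `classes`, `profile`,
#'   `correlation`, `te`, `links` (one element per distance), `truth`.
#' @export
run_pipeline <- function(cfg = sim_config(), alpha = 1e-5, min_frac = 0.95,
                         prob_threshold = 0.95,
                         distances = c(5e5, 1e6), flank = 2000) {
  seg <- simulate_segmentation(cfg)
  pk <- simulate_peaks(cfg, seg$segmentation)
  cov <- simulate_coverage(cfg, pk$atac_peaks)
  te <- simulate_te_table(cfg)
  genes <- simulate_genes(cfg, pk$atac_peaks)

  grouping <- setNames(as.list(names(cfg$state_fractions)),
                       names(cfg$state_fractions))
  enrichment <- enrich_all(pk$chip_peaks, seg$segmentation, grouping,
                           seg$genome)

  sig <- filter_significant(pk$atac_peaks, alpha)
  classes <- classify_peaks(sig, pk$chip_peaks, min_frac)
  over <- classes[mcols(classes)$label == "overlapping"]

  ctrl <- average_tracks(list(cov$ctrl1, cov$ctrl2))
  kd <- average_tracks(list(cov$kd1, cov$kd2))
  profile <- linear_profile(summit_matrix(over, kd, flank),
                            summit_matrix(over, ctrl, flank))

  correlation <- replicate_correlation(cov$ctrl1, cov$ctrl2)

  te_res <- te_diffexp(te$counts, te$condition,
                       prob_threshold = prob_threshold,
                       prob_from_permutation = TRUE, seed = cfg$seed)

  links <- lapply(distances, function(D) link_genes(genes, over, D))
  names(links) <- paste0("D_", format(distances, scientific = FALSE,
                                      trim = TRUE))

  list(params = list(seed = cfg$seed, alpha = alpha, min_frac = min_frac,
                     prob_threshold = prob_threshold, distances = distances,
                     flank = flank),
       enrichment = enrichment,
       classes = classes,
       profile = profile,
       correlation = correlation,
       te = te_res,
       links = links,
       truth = list(te = te$truth,
                    atac_labels = mcols(pk$atac_peaks)$true_label,
                    gene_gaps = mcols(genes)$planted_gap))
}
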