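#' Pair two coverage tracks position-by-position
#'
#' Aligns two per-base tracks by genomic position and applies the zero
#' filter. With `mode = "intersect"` (default) only positions with a nonzero
#' count in *both* tracks are retained — filtering each replicate's zero
#' positions and then merging aligned by position leaves exactly the jointly
#' nonzero positions. `mode = "union"` instead keeps positions nonzero in at
#' least one track, imputing 0 in the other, for sensitivity checks.
#'
#' @param track1,track2 `RleList` coverage tracks on the same genome.
#' @param mode `"intersect"` or `"union"`.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `x`, `y`.
#' @export
pair_and_filter <- function(track1, track2, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  check_same_genome(list(track1, track2))
  per_chrom <- lapply(names(track1), function(chrom) {
    r1 <- track1[[chrom]]; r2 <- track2[[chrom]]
    keep <- if (mode == "intersect") r1 > 0 & r2 > 0 else r1 > 0 | r2 > 0
    n <- sum(keep)
    if (n == 0) return(NULL)
    data.frame(chrom = rep(chrom, n),
               pos = which(as.vector(keep)),
               x = as.numeric(r1[keep]),
               y = as.numeric(r2[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      x = numeric(0), y = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pearson correlation of paired read counts
#'
#' Standard product-moment correlation of the two count vectors.
#'
#' @param paired `data.frame` from [pair_and_filter()] (columns `x`, `y`).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(paired) {
  if (nrow(paired) < 2)
    stop("need at least 2 paired positions, got ", nrow(paired))
  if (stats::var(paired$x) == 0 || stats::var(paired$y) == 0)
    stop("zero variance in a replicate; correlation undefined")
  cor(paired$x, paired$y)
}

#' Subsample paired positions
#'
#' Uniform sample without replacement of `min(n, nrow(paired))` positions;
#' deterministic given `seed`. Used for scatter plots, where drawing every
#' genomic position is pointless.
#'
#' @param paired `data.frame` from [pair_and_filter()].
#' @param n Number of positions to keep (default 100,000).
#' @param seed Integer RNG seed (default 20190828).
#' @return Subset of `paired`, in sampled order.
#' @export
subsample_positions <- function(paired, n = 100000, seed = 20190828) {
  stopifnot(n >= 1)
  if (n >= nrow(paired)) return(paired)
  idx <- with_seed(seed, sample.int(nrow(paired), n))
  out <- paired[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate correlation summary
#'
#' Convenience wrapper: pairs two replicate tracks, applies the zero filter,
#' and reports the Pearson correlation on all retained positions and on a
#' random subsample (both are of interest: the full-track value is the
#' headline number, the subsample matches what a scatter plot shows).
#'
#' @inheritParams pair_and_filter
#' @inheritParams subsample_positions
#' @return List with `n_positions`, `pearson_full`, `pearson_subsample`,
#'   `n_subsampled`, `seed`.
#' @export
replicate_correlation <- function(track1, track2, n = 100000,
                                  seed = 20190828,
                                  mode = c("intersect", "union")) {
  paired <- pair_and_filter(track1, track2, mode)
  sub <- subsample_positions(paired, n, seed)
  list(n_positions = nrow(paired),
       pearson_full = pearson(paired),
       pearson_subsample = pearson(sub),
       n_subsampled = nrow(sub),
       seed = seed)
}
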