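#' Default ChromHMM 15-state grouping
#'
#' Groups the Broad ChromHMM 15-state labels (as distributed for the ENCODE
#' hg19 tracks) into the seven categories used throughout the package:
#' promoter (states 1+2), poised promoter (3), strong enhancer (4+5),
#' poised/weak enhancer (6+7), insulator (8), repressed (12) and
#' heterochromatin (13). Label strings vary between ChromHMM releases, so
#' the grouping is plain data — replace it freely.
#'
#' @return Named list: category name -> character vector of raw state labels.
#' @export
#' @examples
#' names(chromhmm15_grouping())
chromhmm15_grouping <- function() {
  list(
    promoter            = c("1_Active_Promoter", "2_Weak_Promoter"),
    poised_promoter     = "3_Poised_Promoter",
    strong_enhancer     = c("4_Strong_Enhancer", "5_Strong_Enhancer"),
    poised_weak_enhancer = c("6_Weak_Enhancer", "7_Weak_Enhancer"),
    insulator           = "8_Insulator",
    repressed           = "12_Repressed",
    heterochromatin     = "13_Heterochrom/lo"
  )
}

#' Group segmentation states into analysis categories
#'
#' Collapses a labeled segmentation into one merged interval set per output
#' category. Categories need not partition the genome and may overlap in
#' label sets.
#'
#' @param seg A segmentation `GRanges` with a `state` metadata column.
#' @param grouping Named list mapping category name -> character vector of
#'   raw state labels, e.g. [chromhmm15_grouping()].
#' @return Named list of merged `GRanges`, one per category. A category whose
#'   labels occur nowhere in `seg` yields an empty `GRanges` with a warning.
#' @export
group_states <- function(seg, grouping) {
  if (!"state" %in% names(mcols(seg)))
    stop("segmentation must carry a 'state' metadata column")
  vocab <- unique(mcols(seg)$state)
  unknown <- setdiff(unlist(grouping), vocab)
  if (length(unknown))
    stop("grouping refers to state labels absent from the segmentation: ",
         paste(unknown, collapse = ", "))
  out <- lapply(names(grouping), function(cat) {
    sel <- seg[mcols(seg)$state %in% grouping[[cat]]]
    if (!length(sel)) warning("category '", cat, "' matched no intervals")
    gi_merge(sel)
  })
  names(out) <- names(grouping)
  out
}

#' Build the nucleotide-level 2x2 contingency table
#'
#' Cross-classifies every base pair of the effective genome by membership in
#' the peak set and in the category: `a` = bp in both, `b` = bp in peaks
#' only, `c` = bp in category only, `d` = the remaining effective genome.
#' Inputs are merged internally so overlapping records never double-count.
#'
#' @param peaks `GRanges` of peaks.
#' @param category `GRanges` of the chromatin state category (or LADs).
#' @param genome An [oxi_genome()]; its `effective_size` fixes `a+b+c+d`.
#' @return Object of class `oxi_contingency`: list with integers `a`, `b`,
#'   `c`, `d`.
#' @export
#' @examples
#' g <- oxi_genome(c(chr1 = 1000))
#' peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' state <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' build_contingency(peaks, state, g)  # a=50 b=50 c=50 d=850
build_contingency <- function(peaks, category, genome) {
  stopifnot(inherits(genome, "oxi_genome"))
  if (length(peaks) && length(category)) check_chrom_compat(peaks, category)
  a <- total_nt(gi_intersect(peaks, category))
  b <- total_nt(peaks) - a
  cc <- total_nt(category) - a
  d <- genome$effective_size - a - b - cc
  if (d < 0)
    stop("union of peaks and category (", a + b + cc, " bp) exceeds the ",
         "effective genome size (", genome$effective_size,
         " bp); raise effective_size")
  structure(list(a = a, b = b, c = cc, d = d), class = "oxi_contingency")
}

#' @export
print.oxi_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("in peaks", "not in peaks"),
                              c("in category", "not in category")))
  print(m)
  invisible(x)
}

#' Fisher exact test on a nucleotide contingency table
#'
#' Exact hypergeometric test of peak/category association. One-sided
#' `"greater"` (the default) tests overrepresentation: P(X >= a) with all
#' margins fixed. `"two_sided"` sums the point probabilities of all tables
#' (margins fixed) no more probable than the observed one.
#'
#' When any margin is zero the association is undefined; the p-value is
#' reported as 1 with `degenerate = TRUE`. For extremely large tables where
#' two-sided enumeration is infeasible (support above `enum_limit`), the
#' two-sided p-value falls back to doubling the smaller tail, capped at 1,
#' and is flagged via `two_sided_doubling = TRUE`.
#'
#' A caveat inherent to nucleotide-resolution tables: each base pair is
#' treated as an independent trial, while real peaks are contiguous runs of
#' correlated bases, so p-values on multi-bp peaks overstate significance.
#' They are comparable between categories but should be read as scores, not
#' calibrated error rates (see the package vignette).
#'
#' @param table An `oxi_contingency` from [build_contingency()].
#' @param alternative `"greater"` or `"two_sided"`.
#' @param enum_limit Largest two-sided enumeration support (default 5e6).
#' @return List with `p_value`, `odds_ratio` (`ad/bc`, `Inf` when `bc = 0`
#'   and `ad > 0`), `fold_enrichment` (`(a/(a+b)) / ((a+c)/G)`), `degenerate`
#'   and (two-sided only) `two_sided_doubling`.
#' @export
fisher_enrichment <- function(table, alternative = c("greater", "two_sided"),
                              enum_limit = 5e6) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(table, "oxi_contingency"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (any(!is.finite(c(a, b, cc, d))) || any(c(a, b, cc, d) < 0))
    stop("contingency cells must be finite and non-negative")
  G <- a + b + cc + d
  ad <- a * d; bc <- b * cc
  odds_ratio <- if (bc == 0) { if (ad > 0) Inf else NaN } else ad / bc
  fold <- if ((a + b) == 0 || (a + cc) == 0) NaN
          else (a / (a + b)) / ((a + cc) / G)

  degenerate <- (a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0
  if (degenerate)
    return(list(p_value = 1, odds_ratio = odds_ratio,
                fold_enrichment = fold, degenerate = TRUE))

  m <- a + cc   # category bp (white balls)
  n <- b + d    # non-category bp
  k <- a + b    # peak bp (draws)
  if (alternative == "greater") {
    p <- phyper(a - 1, m, n, k, lower.tail = FALSE)
    return(list(p_value = p, odds_ratio = odds_ratio,
                fold_enrichment = fold, degenerate = FALSE))
  }
  lo <- max(0, k - n); hi <- min(k, m)
  doubling <- (hi - lo + 1) > enum_limit
  if (doubling) {
    p_less <- phyper(a, m, n, k)
    p_greater <- phyper(a - 1, m, n, k, lower.tail = FALSE)
    p <- min(1, 2 * min(p_less, p_greater))
  } else {
    support <- lo:hi
    dens <- dhyper(support, m, n, k)
    d_obs <- dhyper(a, m, n, k)
    p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  }
  list(p_value = p, odds_ratio = odds_ratio, fold_enrichment = fold,
       degenerate = FALSE, two_sided_doubling = doubling)
}

#' Enrichment of a peak set across all categories
#'
#' Runs [build_contingency()] + [fisher_enrichment()] for every category of a
#' grouped segmentation. Also usable with a single-category annotation such
#' as lamin-associated domains: pass
#' `grouping = list(LAD = "LAD")` over a segmentation whose `state` column is
#' `"LAD"` everywhere, or call with a pre-grouped `categories` list.
#'
#' p-values are reported raw, one per category, with no multiple-testing
#' correction (each category is a separate genome-level test).
#'
#' @param peaks `GRanges` of peaks (merged internally).
#' @param seg Segmentation `GRanges` with a `state` column, or `NULL` when
#'   `categories` is given.
#' @param grouping Named list as for [group_states()].
#' @param genome An [oxi_genome()].
#' @param alternative Passed to [fisher_enrichment()].
#' @param categories Optional pre-grouped named list of `GRanges`, bypassing
#'   `seg`/`grouping`.
#' @return `data.frame` with one row per category: `category`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `fold_enrichment`, `p_value`.
#' @export
enrich_all <- function(peaks, seg = NULL, grouping = chromhmm15_grouping(),
                       genome, alternative = c("greater", "two_sided"),
                       categories = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(categories)) categories <- group_states(seg, grouping)
  peaks <- gi_merge(peaks)
  rows <- lapply(names(categories), function(cat) {
    tab <- build_contingency(peaks, categories[[cat]], genome)
    fit <- fisher_enrichment(tab, alternative)
    data.frame(category = cat, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               odds_ratio = fit$odds_ratio,
               fold_enrichment = fit$fold_enrichment,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
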