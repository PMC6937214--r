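# Independent oracles used across the suite. All deliberately brute-force:
# dense boolean masks for interval algebra, explicit binomial-coefficient
# sums for the exact test, all-pairs scans for linking. None of them share
# code with the package implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# let data.table syntax work inside testthat-evaluated code
.datatable.aware <- TRUE

# ---- dense boolean-mask interval oracle (single toy chromosome) ----------

# random intervals on one chromosome of length L, as GRanges
rand_intervals <- function(n, L, max_len = 500, chrom = "toy") {
  s <- sample.int(L - max_len, n, replace = TRUE)
  w <- sample.int(max_len, n, replace = TRUE)
  GRanges(chrom, IRanges(s, width = w))
}

# per-base occupancy mask of a GRanges on a chromosome of length L
mask_of <- function(gr, L) {
  m <- logical(L)
  for (i in seq_along(gr)) m[start(gr)[i]:min(L, end(gr)[i])] <- TRUE
  m
}

mask_union_nt <- function(gr, L) sum(mask_of(gr, L))
mask_intersect_nt <- function(a, b, L) sum(mask_of(a, L) & mask_of(b, L))

# per-interval covered fraction against a mask
mask_covered_fraction <- function(x, by, L) {
  m <- mask_of(by, L)
  vapply(seq_along(x), function(i)
    sum(m[start(x)[i]:end(x)[i]]) / width(x)[i], 0)
}

# ---- exact-test enumeration oracle ---------------------------------------

# point probability of a 2x2 table with fixed margins, from binomial
# coefficients directly (no dhyper)
table_point_prob <- function(a, r1, c1, N) {
  exp(lchoose(c1, a) + lchoose(N - c1, r1 - a) - lchoose(N, r1))
}

# one- and two-sided p by full enumeration over the support
enum_fisher <- function(a, b, cc, d) {
  r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
  lo <- max(0, r1 - (N - c1)); hi <- min(r1, c1)
  support <- lo:hi
  pp <- table_point_prob(support, r1, c1, N)
  p_obs <- table_point_prob(a, r1, c1, N)
  list(greater = sum(pp[support >= a]),
       two_sided = sum(pp[pp <= p_obs * (1 + 1e-7)]))
}

# ---- all-pairs gene-peak linking oracle ----------------------------------

# gap in bp between two 1-based closed intervals on possibly different chroms
brute_gap <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(NA_real_)
  if (e1 >= s2 && e2 >= s1) return(0)
  if (s2 > e1) s2 - e1 - 1 else s1 - e2 - 1
}

brute_links <- function(genes, peaks, D) {
  out <- list()
  for (i in seq_along(genes)) for (j in seq_along(peaks)) {
    g <- brute_gap(as.character(seqnames(genes))[i], start(genes)[i],
                   end(genes)[i], as.character(seqnames(peaks))[j],
                   start(peaks)[j], end(peaks)[j])
    if (!is.na(g) && g <= D)
      out[[length(out) + 1]] <- data.frame(gene = i, peak = j,
                                           distance = as.integer(g))
  }
  if (!length(out)) return(data.frame(gene = integer(0), peak = integer(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

# ---- misc ----------------------------------------------------------------

# dense per-base track as a plain numeric vector, from an RleList chromosome
dense_track <- function(track, chrom) as.numeric(track[[chrom]])

toy_genome <- function(L = 1e5, chrom = "toy") {
  oxi_genome(setNames(L, chrom))
}
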