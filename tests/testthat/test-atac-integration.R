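suppressPackageStartupMessages(library(GenomicRanges))

# small helper: GRanges peak with explicit pvalue/summit columns
mk_peak <- function(chrom, start, end, pvalue = NA_real_, summit = NA_real_) {
  g <- GRanges(chrom, IRanges(start, end))
  mcols(g)$pvalue <- pvalue
  mcols(g)$summit <- summit
  g
}

test_that("significance filter is strict at the threshold", {
  p <- c(1e-6, 1e-5, 1e-4)
  peaks <- GRanges("c", IRanges(c(1, 101, 201), width = 50), pvalue = p)
  expect_equal(length(filter_significant(peaks, 1e-5)), 1)
  expect_equal(length(filter_significant(peaks, 1.1)), 3)
  mcols(peaks)$pvalue[2] <- NA
  expect_error(filter_significant(peaks), "missing p-value")
  # retained set equals a brute-force scan on many random peaks
  set.seed(2)
  pv <- runif(1000)
  big <- GRanges("c", IRanges(seq(1, by = 100, length.out = 1000),
                              width = 50), pvalue = pv)
  expect_equal(length(filter_significant(big, 0.3)), sum(pv < 0.3))
})

test_that("overlap classification is strict at 95% and partitions the input", {
  atac <- mk_peak("c", 101, 200)            # [100,200) 0-based
  over96 <- classify_peaks(atac, GRanges("c", IRanges(105, 200)))
  expect_equal(mcols(over96)$covered_fraction, 0.96)
  expect_equal(as.character(mcols(over96)$label), "overlapping")
  exact95 <- classify_peaks(atac, GRanges("c", IRanges(106, 200)))
  expect_equal(mcols(exact95)$covered_fraction, 0.95)
  expect_equal(as.character(mcols(exact95)$label), "orphan")
})

test_that("covered fractions match the mask oracle and labels partition", {
  L <- 1e4
  set.seed(8)
  for (rep in 1:10) {
    atac <- rand_intervals(20, L, 200)
    chip <- rand_intervals(20, L, 300)
    cl <- classify_peaks(atac, chip)
    expect_equal(mcols(cl)$covered_fraction,
                 mask_covered_fraction(atac, chip, L))
    expect_true(all(mcols(cl)$covered_fraction >= 0 &
                    mcols(cl)$covered_fraction <= 1))
    expect_equal(sum(mcols(cl)$label == "overlapping") +
                 sum(mcols(cl)$label == "orphan"), length(atac))
    # adding chip peaks never decreases any covered fraction
    more <- classify_peaks(atac, c(chip, rand_intervals(10, L, 300)))
    expect_true(all(mcols(more)$covered_fraction >=
                    mcols(cl)$covered_fraction - 1e-12))
  }
})

test_that("averaging replicates is the per-position mean with absent = 0", {
  g <- toy_genome(1000)
  t1 <- methods::as(list(toy = Rle(c(0, 4, 0, 2), c(100, 300, 500, 100))),
                    "SimpleRleList")
  zero <- methods::as(list(toy = Rle(0, 1000)), "SimpleRleList")
  expect_identical(average_tracks(list(t1, t1)), t1)
  half <- average_tracks(list(t1, zero))
  expect_equal(dense_track(half, "toy"), dense_track(t1, "toy") / 2)
  t_other <- methods::as(list(elsewhere = Rle(1, 1000)), "SimpleRleList")
  expect_error(average_tracks(list(t1, t_other)), "same genome")
})

test_that("bedGraph round-trips through run-length compression", {
  g <- toy_genome(2000)
  set.seed(3)
  v <- rpois(2000, 0.5)
  tr <- methods::as(list(toy = Rle(v)), "SimpleRleList")
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, g)
  expect_equal(dense_track(back, "toy"), as.numeric(v))
})

test_that("summit matrix equals the dense-array oracle, pads out-of-bounds with 0", {
  L <- 5000
  g <- toy_genome(L)
  set.seed(12)
  v <- rpois(L, 2)
  tr <- methods::as(list(toy = Rle(v)), "SimpleRleList")
  peaks <- mk_peak("toy", c(2000, 3000, 20), c(2200, 3200, 220),
                   summit = c(2100, 3100, 120))
  m <- summit_matrix(peaks, tr, flank = 150)
  expect_equal(dim(m), c(3, 301))
  for (i in 1:2)
    expect_equal(m[i, ], v[(mcols(peaks)$summit[i] - 150):
                           (mcols(peaks)$summit[i] + 150)],
                 ignore_attr = TRUE)
  # third peak truncated on the left: offsets before base 1 are zero
  expect_true(attr(m, "truncated")[3])
  expect_equal(m[3, 1:31], rep(0, 31), ignore_attr = TRUE)  # offsets < base 1
  expect_equal(m[3, 32:301], v[1:270], ignore_attr = TRUE)
})

test_that("constant tracks give constant matrices; bumps are summit-symmetric", {
  L <- 3000
  tr <- methods::as(list(toy = Rle(7, L)), "SimpleRleList")
  pk <- mk_peak("toy", 1000, 1400, summit = 1200)
  m <- summit_matrix(pk, tr, flank = 100)
  expect_true(all(m == 7))
  bump <- exp(-((1:L - 1500)^2) / (2 * 50^2))
  tb <- methods::as(list(toy = Rle(bump)), "SimpleRleList")
  mb <- summit_matrix(mk_peak("toy", 1300, 1700, summit = 1500), tb, 200)
  expect_equal(mb[1, ], rev(mb[1, ]), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("midpoint fallback is used when no summit is recorded", {
  L <- 2000
  v <- seq_len(L)
  tr <- methods::as(list(toy = Rle(as.numeric(v))), "SimpleRleList")
  pk <- GRanges("toy", IRanges(501, 700))   # midpoint floor((501+700)/2)=600
  m <- summit_matrix(pk, tr, flank = 0)
  expect_equal(as.numeric(m), 600)
})

test_that("metaprofile is control-summit-normalized and linear", {
  set.seed(4)
  ctrl <- matrix(rpois(20 * 41, 5) + 1, 20, 41)
  attr(ctrl, "offsets") <- -20:20
  ctrl[, 21] <- ctrl[, 21] + 30    # summit-peaked control
  kd_same <- ctrl
  pr <- linear_profile(kd_same, ctrl)
  expect_equal(pr$ctrl[pr$offset == 0], 1)
  expect_equal(pr$kd, pr$ctrl)
  kd2 <- 2 * ctrl
  attr(kd2, "offsets") <- -20:20
  pr2 <- linear_profile(kd2, ctrl)
  expect_equal(pr2$kd, 2 * pr2$ctrl, tolerance = 1e-12)
  zero <- ctrl; zero[, 21] <- 0
  expect_error(linear_profile(kd2, zero), "summit column-sum is zero")
})
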