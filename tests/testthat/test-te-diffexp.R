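# literal step-by-step TMM oracle for a single sample against a reference;
# independent of the package implementation
oracle_tmm_one <- function(ys, yr, ns, nr, trim_m = 0.3, trim_a = 0.05) {
  keep <- ys > 0 & yr > 0
  ys <- ys[keep]; yr <- yr[keep]
  M <- log2((ys / ns) / (yr / nr))
  A <- 0.5 * log2((ys / ns) * (yr / nr))
  w <- 1 / ((ns - ys) / (ns * ys) + (nr - yr) / (nr * yr))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
}

toy_counts <- function() {
  matrix(c(1000, 2000, 500, 4000, 80, 300,
           1500, 1800, 900, 5200, 60, 600,
           1100, 2100, 450, 3900, 85, 310,
           2900, 4100, 1000, 8100, 170, 650),
         nrow = 6,
         dimnames = list(paste0("fam", 1:6), c("c1", "c2", "k1", "k2")))
}

test_that("TMM factors are 1 for identical or purely depth-scaled libraries", {
  x <- toy_counts()[, c(1, 1, 1, 1)]
  colnames(x) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(x)), rep(1, 4))
  y <- cbind(s1 = toy_counts()[, 1], s2 = 2 * toy_counts()[, 1])
  expect_equal(unname(tmm_factors(y)), c(1, 1))
})

test_that("TMM factors match the step-by-step oracle on the 6-family table", {
  x <- toy_counts()
  lib <- colSums(x)
  f75 <- apply(x, 2, function(u) quantile(u, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- vapply(1:4, function(s)
    oracle_tmm_one(x[, s], x[, ref], lib[s], lib[ref]), 0)
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(tmm_factors(x)), unname(expected), tolerance = 1e-12)
})

test_that("TMM factors agree with edgeR and have geometric mean exactly 1", {
  skip_if_not_installed("edgeR")
  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(rnbinom(40 * 4, mu = exp(runif(40, 3, 10)), size = 20),
                nrow = 40, dimnames = list(NULL, paste0("s", 1:4)))
    x <- x[rowSums(x == 0) == 0, , drop = FALSE]
    mine <- tmm_factors(x)
    ref <- edgeR::calcNormFactors(x, method = "TMM")
    expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
    expect_equal(exp(mean(log(mine))), 1, tolerance = 1e-12)
    # invariant to a global rescaling of all counts
    expect_equal(unname(tmm_factors(x * 3)), unname(mine), tolerance = 1e-10)
  }
})

test_that("condition means use common normalized library size", {
  x <- toy_counts()
  cond <- c("control", "control", "kd", "kd")
  f <- tmm_factors(x)
  cm <- condition_means(x, cond, f)
  eff <- colSums(x) * f
  norm <- sweep(x, 2, eff, "/") * mean(eff)
  expect_equal(cm$ctrl_mean, unname(rowMeans(norm[, 1:2])))
  expect_equal(cm$kd_mean, unname(rowMeans(norm[, 3:4])))
  # duplicate identical replicates: mean equals the replicate value
  x2 <- x[, c(1, 1, 3, 3)]
  colnames(x2) <- paste0("s", 1:4)
  f2 <- setNames(rep(1, 4), colnames(x2))
  cm2 <- condition_means(x2, cond, f2)
  eff2 <- colSums(x2) * f2
  expect_equal(cm2$ctrl_mean, unname(x2[, 1] / eff2[1] * mean(eff2)))
})

test_that("log2fc orientation is KD over control with published rounding", {
  expect_equal(round_half_away(log2fc(3601718.96, 3714313.36), 2), 0.04)
  expect_equal(round_half_away(log2fc(8958641.10, 9448789.20), 2), 0.08)
  expect_equal(log2fc(5, 5), 0)
  expect_equal(log2fc(0, 3), Inf)
  expect_equal(log2fc(3, 0), -Inf)
  expect_true(is.nan(log2fc(0, 0)))
})

test_that("swapping condition labels negates every log2 fold change", {
  x <- toy_counts()
  f <- tmm_factors(x)
  a <- condition_means(x, c("control", "control", "kd", "kd"), f)
  b <- condition_means(x, c("kd", "kd", "control", "control"), f)
  expect_equal(log2fc(a$ctrl_mean, a$kd_mean),
               -log2fc(b$ctrl_mean, b$kd_mean), tolerance = 1e-12)
})

test_that("significance flag is strict at the probability threshold", {
  df <- data.frame(family = c("a", "b", "c"), prob = c(0.95, 1.00, 0.951))
  out <- significance_filter(df)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE))
  expect_error(significance_filter(data.frame(prob = c(0.2, NA))), "missing|incomplete")
})

test_that("permutation probabilities: planted change found, flat data gives 0", {
  cfg <- sim_config(seed = 5, te_planted_lfc = c(FAM01 = 2),
                    te_dispersion = 0.005)
  te <- simulate_te_table(cfg)
  pr <- prob_from_permutation(te$counts, te$condition, seed = 1)
  expect_gt(pr["FAM01"], 0.95)
  flat <- matrix(100, 5, 4, dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  pf <- prob_from_permutation(flat, c("control", "control", "kd", "kd"))
  expect_equal(unname(pf), rep(0, 5))
  expect_error(prob_from_permutation(flat[, 1:2], c("control", "kd")),
               "insufficient replicates")
})

test_that("planted TE log2 fold change of +1 is recovered within 0.1 (median over seeds)", {
  est <- vapply(1:25, function(s) {
    te <- simulate_te_table(sim_config(seed = s))
    res <- te_diffexp(te$counts, te$condition)
    res$log2fc[res$family == "FAM01"]
  }, 0)
  expect_lt(abs(median(est) - 1), 0.1)
})

test_that("published table: recomputed log2FC matches print for spot-checked families", {
  tab <- te_published_table()
  expect_equal(nrow(tab), 70)
  for (fam in c("Alu", "RNA", "ERVK", "MIR", "hAT", "SVA_B")) {
    row <- tab[tab$family == fam, ]
    expect_equal(round_half_away(log2fc(row$ctrl_mean, row$kd_mean), 2),
                 row$log2fc, info = fam)
  }
})
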