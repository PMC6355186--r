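# Group statistics and profiling computations.

test_that("two-sample t-test matches the textbook Welch formula", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    got <- twoSampleTTest(a, b)
    ref <- oracleWelch(a, b)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("degenerate t-test inputs follow the stated conventions", {
  expect_equal(twoSampleTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # paired identical series: all differences zero, p = 1
  expect_equal(twoSampleTTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p, 1)
  # zero variance with a nonzero difference
  expect_equal(twoSampleTTest(c(2, 2, 2), c(5, 5, 5))$p, 0)
  expect_error(twoSampleTTest(1, c(1, 2)), "at least 2")
  expect_error(twoSampleTTest(c(1, 2), c(1, 2, 3), paired = TRUE), "equal lengths")
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  # p(i) * m / i, cumulative minimum from the largest p
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bhAdjust(c(0.2, 1.4)), "0, 1")
})

test_that("Dunnett with one treatment group reduces to the pooled t-test", {
  set.seed(12)
  a <- rnorm(6); b <- rnorm(6, 1)
  res <- dunnettVsControl(c(a, b), rep(c("ctl", "trt"), each = 6), "ctl",
                          nDraws = 2e5, seed = 5)
  pooled <- t.test(b, a, var.equal = TRUE)$p.value
  expect_lt(abs(res$p_adjusted - pooled), 0.01)
})

test_that("Dunnett adjusted p never undercuts the unadjusted p", {
  set.seed(13)
  for (i in 1:5) {
    v <- rnorm(20)
    g <- rep(c("ctl", "t1", "t2", "t3"), each = 5)
    res <- dunnettVsControl(v, g, "ctl", seed = i)
    expect_true(all(res$p_adjusted >= res$p))
  }
})

test_that("Dunnett agrees with an independent implementation", {
  set.seed(14)
  v <- rnorm(16, rep(c(0, 0.5, 1, 2), each = 4))
  g <- factor(rep(c("ctl", "t1", "t2", "t3"), each = 4),
              levels = c("ctl", "t1", "t2", "t3"))
  ours <- dunnettVsControl(v, g, "ctl", nDraws = 2e5, seed = 2)
  ref <- summary(multcomp::glht(stats::aov(v ~ g),
                                linfct = multcomp::mcp(g = "Dunnett")))
  refP <- as.numeric(ref$test$pvalues)
  expect_lt(max(abs(ours$p_adjusted - refP)), 0.01)
})

test_that("Dunnett detects a large planted shift", {
  set.seed(15)
  v <- c(rnorm(4), rnorm(4), rnorm(4, 3))  # 3-pooled-SD shift in one group
  g <- rep(c("ctl", "t1", "t2"), each = 4)
  res <- dunnettVsControl(v, g, "ctl", seed = 3)
  expect_true(res$significant[res$comparison == "t2 - ctl"])
  expect_false(res$significant[res$comparison == "t1 - ctl"])
})

test_that("Tukey-Kramer matches stats::TukeyHSD", {
  set.seed(16)
  v <- rnorm(18, rep(c(0, 1, 3), each = 6))
  g <- rep(c("a", "b", "c"), each = 6)
  ours <- tukeyKramer(v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  # align comparisons (TukeyHSD labels "b-a" style)
  refP <- ref[, "p adj"]
  getP <- function(i, j) {
    r <- ours[ours$comparison %in% c(paste(i, "-", j), paste(j, "-", i)), ]
    r$p_adjusted
  }
  expect_equal(getP("b", "a"), unname(refP["b-a"]), tolerance = 1e-8)
  expect_equal(getP("c", "a"), unname(refP["c-a"]), tolerance = 1e-8)
  expect_equal(getP("c", "b"), unname(refP["c-b"]), tolerance = 1e-8)
})

test_that("Tukey-Kramer separates only the shifted group", {
  set.seed(17)
  v <- c(rnorm(3, 0, 1e-3), rnorm(3, 0, 1e-3), rnorm(3, 10, 1e-3))
  g <- rep(c("g1", "g2", "g3"), each = 3)
  res <- tukeyKramer(v, g)
  involves3 <- grepl("g3", res$comparison)
  expect_true(all(res$significant[involves3]))
  expect_false(any(res$significant[!involves3]))
  # two groups: decision agrees with the pooled t-test
  v2 <- rnorm(8, rep(c(0, 2), each = 4)); g2 <- rep(c("a", "b"), each = 4)
  tk <- tukeyKramer(v2, g2)
  expect_equal(tk$p_adjusted, tk$p, tolerance = 1e-8)
})

test_that("fold change, evidence filter and SNP density follow the rules", {
  expect_identical(foldChangeClassify(2, 1), "up")
  expect_identical(foldChangeClassify(0.5, 1), "down")
  expect_identical(foldChangeClassify(1, 1), "unchanged")
  expect_error(foldChangeClassify(1, 0), "denominator")

  rec <- data.frame(unique_peptides = c(3, 1, 2, 2),
                    fdr = c(0.005, 0.001, 0.01, 0.0099))
  kept <- proteinEvidenceFilter(rec)
  expect_equal(rownames(kept), c("1", "4"))  # >=2 peptides AND fdr < 1%
  expect_error(proteinEvidenceFilter(data.frame(fdr = 0.1)), "columns")

  expect_equal(snpDensity(4, 2)$per_kb, 2)
  expect_equal(snpDensity(0, 5)$per_kb, 0)
  expect_equal(snpDensity(7, 3.5)$per_kb, 2)
  expect_equal(snpDensity(4, 2)$percent, 200)
  expect_error(snpDensity(1, 0), "length")
})

test_that("CV uses the population convention and is scale-free", {
  expect_equal(coefficientOfVariation(rep(4, 6)), 0)
  expect_equal(coefficientOfVariation(c(5, 15)), 0.5)  # pop sd 5, mean 10
  set.seed(18)
  x <- rlnorm(20)
  expect_equal(coefficientOfVariation(3.3 * x), coefficientOfVariation(x),
               tolerance = 1e-12)
  expect_error(coefficientOfVariation(c(-5, 1)), "positive")
})

test_that("SVD PCA matches an eigendecomposition of the covariance", {
  set.seed(19)
  x <- matrix(rnorm(60), 10, 6)
  res <- pcaSvd(x)
  expect_equal(sum(res$varianceExplained), 1, tolerance = 1e-12)
  ev <- eigen(cov(x))
  # eigenvalues of the covariance = d^2 / (n - 1)
  expect_equal(res$d^2 / 9, ev$values[1:6], tolerance = 1e-8)
  for (k in 1:6) {
    expect_equal(abs(sum(res$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # full reconstruction of the centered matrix
  ctr <- sweep(x, 2, colMeans(x))
  expect_equal(res$scores %*% t(res$loadings), ctr, tolerance = 1e-8)
})

test_that("PCA handles collinear and missing data", {
  x <- cbind(1:8, 2 * (1:8))
  res <- pcaSvd(x)
  expect_equal(res$varianceExplained[1], 1, tolerance = 1e-12)

  set.seed(20)
  xm <- matrix(rnorm(50), 10, 5)
  xm[2, 3] <- NA; xm[7, 1] <- NA
  resm <- pcaSvd(xm)                       # mean imputation
  expect_equal(sum(resm$varianceExplained), 1, tolerance = 1e-12)
  resi <- pcaSvd(xm, impute = "iterative") # iterative refinement
  expect_equal(sum(resi$varianceExplained), 1, tolerance = 1e-12)
  expect_error(pcaSvd(xm[1, , drop = FALSE]), "at least 2")
})

test_that("complete-linkage clustering reproduces hand-traced merges", {
  hc0 <- hclustCompleteEuclidean(matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE))
  expect_equal(hc0$height, 0)
  hc <- hclustCompleteEuclidean(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(hc$height, c(1, 10))  # (0,1) at 1, then max-distance 10
  set.seed(22)
  hcr <- hclustCompleteEuclidean(matrix(rnorm(40), 10, 4))
  expect_true(all(diff(hcr$height) >= 0))  # ultrametric heights
  expect_error(hclustCompleteEuclidean(matrix(1, 1, 3)), "at least 2")
})

test_that("serum-batch pairing finds no systematic shift in a null table", {
  cfg <- simConfig(seed = 7)
  sb <- simulateSerumBatches(cfg)
  res <- serumBatchPairedTests(sb$concentrations)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_adjusted >= res$p - 1e-12))
  # a genuine global batch shift is detected
  shifted <- sb$concentrations
  shifted[, 2] <- shifted[, 2] * 1.5
  expect_true(any(serumBatchPairedTests(shifted)$significant))
})
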