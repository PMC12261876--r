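## Independent oracles used below:
##  - ICC from stats::aov mean squares
##  - Wilcoxon two-sided p from full 2^n sign enumeration
##  - overlap from explicit voxel-by-voxel counting

iccOracle <- function(x1, x2) {
  n <- length(x1)
  dat <- data.frame(y = c(x1, x2),
                    subj = factor(rep(seq_len(n), 2)),
                    cond = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + cond, data = dat))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

wilcoxonOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
}

overlapOracle <- function(v1, v2, mask) {
  nvv <- ndd <- nv1 <- nv2 <- nd1 <- nd2 <- 0
  for (i in which(mask)) {
    if (v1[i] && v2[i]) nvv <- nvv + 1
    if (!v1[i] && !v2[i]) ndd <- ndd + 1
    if (v1[i]) nv1 <- nv1 + 1 else nd1 <- nd1 + 1
    if (v2[i]) nv2 <- nv2 + 1 else nd2 <- nd2 + 1
  }
  2 * (nvv + ndd) / (nv1 + nv2 + nd1 + nd2) * 100
}

test_that("Bland-Altman bias and limits of agreement", {
  ba <- blandAltman(c(0, 2, 4), c(0, 0, 0))
  expect_equal(ba$bias, 2)
  expect_equal(ba$loaLow, 2 - 1.96 * 2)
  expect_equal(ba$loaHigh, 2 + 1.96 * 2)
  ## identical conditions
  ba0 <- blandAltman(1:5, 1:5)
  expect_equal(c(ba0$bias, ba0$loaLow, ba0$loaHigh), c(0, 0, 0))
  ## constant differences
  ba1 <- blandAltman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(c(ba1$bias, ba1$loaLow, ba1$loaHigh), c(1, 1, 1))
  expect_error(blandAltman(1, 1), "at least 2")
})

test_that("Bland-Altman is antisymmetric under condition swap", {
  set.seed(3)
  x1 <- rnorm(20); x2 <- rnorm(20)
  a <- blandAltman(x1, x2); b <- blandAltman(x2, x1)
  expect_equal(a$bias, -b$bias)
  expect_equal(a$loaLow, -b$loaHigh)
  expect_equal(a$loaHigh, -b$loaLow)
})

test_that("between-measurement CoV uses the two-value sample sd", {
  expect_equal(pairwiseCoV(10, 10)$median, 0)
  expect_equal(pairwiseCoV(9, 11)$median, 100 * sqrt(2) / 10)
  cohort <- pairwiseCoV(c(5, 5, 5), c(5, 5, 5))
  expect_equal(cohort$median, 0)
  z <- pairwiseCoV(c(1, -1), c(2, 1))
  expect_equal(z$flagged, 2L)
  expect_true(is.na(z$perSubject[2]))
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle on fuzz cases", {
  set.seed(2026)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    subj <- rnorm(n, sd = runif(1, 0.5, 3))
    x1 <- subj + rnorm(n)
    x2 <- subj + rnorm(n) + runif(1, -1, 1)
    expect_lt(abs(iccAbsoluteAgreement(x1, x2) - iccOracle(x1, x2)), 1e-10)
  }
  ## perfect agreement with between-subject spread
  expect_equal(iccAbsoluteAgreement(1:5, 1:5), 1)
  expect_error(iccAbsoluteAgreement(rep(1, 5), rep(1, 5)), "undefined")
  expect_error(iccAbsoluteAgreement(1:2, 1:2), "at least 3")
})

test_that("ICC recovers a designed reliability of 0.9", {
  set.seed(99)
  n <- 10000
  subj <- rnorm(n, sd = 3)
  icc <- iccAbsoluteAgreement(subj + rnorm(n), subj + rnorm(n))
  expect_lt(abs(icc - 0.9), 0.02)
  ## independent conditions: ICC near 0
  icc0 <- iccAbsoluteAgreement(rnorm(n), rnorm(n))
  expect_lt(abs(icc0), 0.05)
})

test_that("ICC and effect-size interpretation scales", {
  expect_equal(interpretICC(0.35), "fair")
  expect_equal(interpretICC(0.70), "substantial")
  expect_equal(interpretICC(0.50), "moderate")
  expect_equal(interpretICC(-0.1), "less than chance")
  expect_equal(interpretICC(1), "almost perfect")
  expect_equal(interpretEffectSize(0.5), "medium")
  expect_equal(interpretEffectSize(-1.3), "very large")
  expect_equal(interpretEffectSize(0.1), "very small")
  expect_equal(interpretEffectSize(0.005), "negligible")
  expect_equal(interpretEffectSize(2.5), "huge")
})

test_that("paired Cohen's d behaves and recovers a designed shift", {
  expect_equal(cohensDPaired(1:5, 1:5), 0)
  set.seed(4)
  x1 <- rnorm(30); x2 <- rnorm(30)
  expect_equal(cohensDPaired(x1, x2), -cohensDPaired(x2, x1))
  ## designed standardised shift of 0.5
  set.seed(8)
  d <- rnorm(10000, mean = 0.5, sd = 1)
  expect_lt(abs(cohensDPaired(d, rep(0, 10000)) - 0.5), 0.05)
  expect_error(cohensDPaired(c(2, 3, 4), c(1, 2, 3)), "undefined")
})

test_that("Wilcoxon p matches full sign enumeration for all n <= 8", {
  ## no ties
  set.seed(5)
  for (n in 1:8) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      d[d == 0] <- 0.5
      got <- wilcoxonSignedRank(d)$p
      expect_equal(got, wilcoxonOracle(d), tolerance = 1e-12,
                   info = paste("n =", n))
    }
    ## with ties in |d|
    dTied <- sample(c(-2, -1, 1, 2), n, replace = TRUE)
    expect_equal(wilcoxonSignedRank(dTied)$p, wilcoxonOracle(dTied),
                 tolerance = 1e-12)
  }
  ## frozen examples
  expect_equal(wilcoxonSignedRank(c(1, 2, 3))$p, 0.25)
  expect_equal(wilcoxonSignedRank(c(-1, 1))$p, 1)
  z <- wilcoxonSignedRank(rep(0, 5))
  expect_equal(z$p, 1)
  expect_true(z$allZero)
})

test_that("Wilcoxon agrees with stats::wilcox.test when it is exact", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    x1 <- rnorm(n); x2 <- rnorm(n)
    ref <- stats::wilcox.test(x1, x2, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxonSignedRank(x1, x2)$p, ref, tolerance = 1e-12)
  }
})

test_that("spatial overlap matches brute-force counting and its bounds", {
  ## frozen 4-voxel case: 2(1+2)/8 * 100 = 75
  m <- array(TRUE, c(4, 1, 1))
  v1 <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  v2 <- array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1))
  expect_equal(spatialOverlap(v1, v2, m), 75)
  expect_equal(spatialOverlap(v1, v1, m), 100)
  expect_equal(spatialOverlap(v1, !v1, m), 0)
  set.seed(7)
  for (i in 1:100) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(1:3, 1))
    mask <- array(runif(prod(d)) < 0.8, d)
    if (!any(mask)) next
    a <- array(runif(prod(d)) < 0.6, d)
    b <- array(runif(prod(d)) < 0.6, d)
    got <- spatialOverlap(a, b, mask)
    expect_identical(got, overlapOracle(a, b, mask))
    expect_identical(got, spatialOverlap(b, a, mask))  # symmetry
    expect_true(got >= 0 && got <= 100)
  }
  expect_error(spatialOverlap(v1, v2, array(FALSE, c(4, 1, 1))),
               "empty mask")
})

test_that("age matching is optimal and reports exclusions", {
  am <- ageMatch(c(25), c(24, 60))
  expect_equal(nrow(am$pairs), 1)
  expect_equal(am$pairs$ageB, 24)
  expect_equal(am$medianAbsDiff, 1)
  expect_equal(am$excluded, "B2")
  ## identical lists: perfect matching
  am2 <- ageMatch(c(30, 40, 50), c(30, 40, 50))
  expect_equal(am2$medianAbsDiff, 0)
  expect_equal(length(am2$excluded), 0)
  ## cohort sizes 24 vs 26 -> 24 pairs, 2 exclusions
  set.seed(9)
  am3 <- ageMatch(runif(24, 20, 40), runif(26, 20, 60))
  expect_equal(nrow(am3$pairs), 24)
  expect_equal(length(am3$excluded), 2)
})

test_that("age matching equals exhaustive-search minimum on small cohorts", {
  bruteMin <- function(a, b) {
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    combs <- utils::combn(length(b), length(a), simplify = FALSE)
    best <- Inf
    for (cb in combs) {
      perms <- permutations(length(a))
      for (p in perms)
        best <- min(best, sum(abs(a - b[cb[p]])))
    }
    best
  }
  permutations <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n))
      for (p in permutations(n - 1))
        out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    out
  }
  set.seed(10)
  for (rep in 1:8) {
    a <- sample(18:70, sample(2:4, 1))
    b <- sample(18:70, sample(3:5, 1), replace = TRUE)
    expect_equal(ageMatch(a, b)$totalAbsDiff, bruteMin(a, b))
  }
})

test_that("percent change follows the reference convention", {
  expect_equal(percentChange(100, 118), 18)
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(2, 1), -50)
  expect_error(percentChange(0, 1), "zero reference")
})
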