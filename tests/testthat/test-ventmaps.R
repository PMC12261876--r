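## A tiny handmade phase-resolved image: 2x2x1 voxels, controllable signals.
tinyImage <- function(sExp, sInsp, sMid = (sExp + sInsp) / 2) {
  d <- c(2, 2, 1)
  data <- array(NA_real_, c(d, 3))
  data[, , , 1] <- sExp
  data[, , , 2] <- sMid
  data[, , , 3] <- sInsp
  PhaseResolvedImage(data, c(10, 10, 10), expIdx = 1, inspIdx = 3,
                     phaseU = c(0, 0.5, 1))
}

fullMask <- function() array(TRUE, c(2, 2, 1))

test_that("RVent follows the printed signal formula", {
  ## S_exp = 1.0, S_insp = 0.8 (ref = insp) -> static RVent = 0.2
  rv <- computeRVentCycle(tinyImage(1.0, 0.8), fullMask())
  expect_true(all(abs(rv$static - 0.2) < 1e-12))
  ## RVent at end-expiration is identically zero
  expect_true(all(abs(rv$cycle[, , , 1]) < 1e-12))
  ## phase-constant signal -> zero everywhere
  rv0 <- computeRVentCycle(tinyImage(1, 1, 1), fullMask())
  expect_true(all(abs(rv0$cycle) < 1e-12))
  ## non-positive signal is a data error naming the count
  expect_error(computeRVentCycle(tinyImage(1, -1), fullMask()),
               "data error.*8 voxel-phase")
})

test_that("static RVent of a synthetic voxel equals sv/(1+sv)", {
  m <- noiseFreeMeasurement(svMean = 0.25, het = 0)
  rv <- computeRVentCycle(m@images, analysisMask(m))
  vals <- rv$static[analysisMask(m)]
  expect_true(all(abs(vals - 0.2) < 1e-9))
})

test_that("map summaries use in-mask mean and population CoV", {
  map <- array(c(1, 3, 1, 3), c(2, 2, 1))
  s <- summarizeMap(map, fullMask())
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["cov"]), 50)  # population sd 1, mean 2
  ## sample convention optional
  s2 <- summarizeMap(map, fullMask(), sdType = "sample")
  expect_equal(unname(s2["cov"]), 100 * sd(c(1, 3, 1, 3)) / 2)
  const <- array(5, c(2, 2, 1))
  expect_equal(unname(summarizeMap(const, fullMask())["cov"]), 0)
  expect_error(summarizeMap(map, array(FALSE, c(2, 2, 1))), "empty mask")
})

test_that("VVP_RVent thresholds at 40% of the 90th percentile, strictly", {
  map <- array(0, c(10, 1, 1))
  map[1:10] <- 1:10
  mask <- array(TRUE, c(10, 1, 1))
  v <- vvpRVent(map, mask)
  expect_equal(v$threshold, 0.4 * 9.1)  # linear-interpolation percentile
  expect_equal(v$vvp, 70)
  ## constant positive map: all strictly above 0.4c
  expect_equal(vvpRVent(array(2, c(2, 2, 1)), fullMask())$vvp, 100)
  ## all-zero map: threshold 0, none strictly above
  expect_equal(vvpRVent(array(0, c(2, 2, 1)), fullMask())$vvp, 0)
})

test_that("flow-volume loops are closed and scale linearly", {
  m <- noiseFreeMeasurement(svMean = 0.25, het = 1)
  mask <- analysisMask(m)
  rv <- computeRVentCycle(m@images, mask)
  fvl <- buildFVL(rv, mask)
  ## cyclic flow sums to zero for every voxel (closed loop)
  expect_lt(max(abs(rowSums(fvl$flow))), 1e-9)
  ## volume starts at end-expiration where RVent = 0
  expect_lt(max(abs(fvl$volume[, 1])), 1e-9)
  ## doubling RVent doubles volume and flow
  rv2 <- rv
  rv2$cycle <- rv$cycle * 2
  fvl2 <- buildFVL(rv2, mask)
  expect_equal(fvl2$volume, fvl$volume * 2, tolerance = 1e-12)
  expect_equal(fvl2$flow, fvl$flow * 2, tolerance = 1e-12)
})

test_that("FVL-CM is 1 for homogeneous dynamics and handles edge cases", {
  m <- noiseFreeMeasurement(svMean = 0.25, het = 1)
  mask <- analysisMask(m)
  fvl <- buildFVL(computeRVentCycle(m@images, mask), mask)
  cm <- fvlCorrelationMap(fvl, mask)
  ## noise-free loops are all scalar multiples of the same waveform
  expect_true(all(abs(cm$map[mask] - 1) < 1e-9))
  ## negated loop -> -1; scaled loop -> 1 (correlation scale-invariance)
  fvl$volume[1, ] <- -fvl$refVolume
  fvl$flow[1, ] <- -fvl$refFlow
  fvl$volume[2, ] <- 2 * fvl$refVolume
  fvl$flow[2, ] <- 2 * fvl$refFlow
  cm2 <- fvlCorrelationMap(fvl, mask)
  vox <- fvl$voxels
  expect_equal(cm2$map[vox[1]], -1, tolerance = 1e-9)
  expect_equal(cm2$map[vox[2]], 1, tolerance = 1e-9)
  ## zero-variance voxel flagged with FVL-CM 0
  fvl$volume[3, ] <- 0
  fvl$flow[3, ] <- 0
  cm3 <- fvlCorrelationMap(fvl, mask)
  expect_equal(cm3$map[vox[3]], 0)
  expect_true(vox[3] %in% cm3$flagged)
})

test_that("VVP_FVL-CM uses a strict 0.9 threshold", {
  map <- array(c(1, 1, 1, 1), c(2, 2, 1))
  expect_equal(vvpFVLCM(map, fullMask())$vvp, 100)
  map2 <- array(c(0.95, 0.95, 0.5, 0.5), c(2, 2, 1))
  expect_equal(vvpFVLCM(map2, fullMask())$vvp, 50)
  ## boundary: exactly 0.9 is not ventilated
  expect_equal(vvpFVLCM(array(0.9, c(2, 2, 1)), fullMask())$vvp, 0)
})

test_that("tidal volume arithmetic and inversion warning", {
  a <- array(FALSE, c(4, 4, 4)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[1:2, , ] <- TRUE
  expect_equal(as.numeric(tidalVolume(a, b, c(10, 10, 10))), 16)
  expect_equal(as.numeric(tidalVolume(a, a, c(10, 10, 10))), 0)
  expect_warning(tv <- tidalVolume(b, a, c(10, 10, 10)), "negative")
  expect_equal(as.numeric(tv), -16)
  expect_true(attr(tv, "inverted"))
})

test_that("measurement summary hits closed forms on phantoms", {
  ## constant-sv phantom
  s <- summarizeMeasurement(noiseFreeMeasurement(svMean = 0.25, het = 0))
  expect_lt(abs(s@meanRVent - 0.2), 1e-9)
  expect_lt(s@covRVent, 1e-9)
  expect_equal(s@vvpRVent, 100)
  expect_equal(s@vvpFVLCM, 100)
  ## zero-ventilation phantom: RVent 0 everywhere, VVP_RVent 0; the FVL
  ## reference loop is degenerate, so FVL-CM falls back to 0 with a warning
  expect_warning(
    s0 <- summarizeMeasurement(noiseFreeMeasurement(svMean = 0, het = 0)),
    "zero variance")
  expect_lt(abs(s0@meanRVent), 1e-12)
  expect_equal(s0@vvpRVent, 0)
  ## determinism
  s2 <- summarizeMeasurement(noiseFreeMeasurement(svMean = 0.25, het = 0))
  expect_identical(as.data.frame(s), as.data.frame(s2))
})

test_that("summaries are invariant to global intensity scaling", {
  m <- noiseFreeMeasurement(svMean = 0.25, het = 1)
  m2 <- m
  m2@images@data <- m@images@data * 7.3
  s1 <- as.data.frame(summarizeMeasurement(m))
  s2 <- as.data.frame(summarizeMeasurement(m2))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("expected VVP_RVent is non-increasing in noise level", {
  ## homogeneous static map + increasing noise
  d <- c(12, 12, 12)
  mask <- array(TRUE, d)
  base <- array(0.2, d)
  meanVVP <- sapply(c(0.01, 0.05, 0.1), function(sig) {
    mean(sapply(1:10, function(r) {
      set.seed(100 * sig + r)
      vvpRVent(base + array(rnorm(prod(d), sd = sig), d), mask)$vvp
    }))
  })
  expect_true(all(diff(meanVVP) <= 0))
})
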