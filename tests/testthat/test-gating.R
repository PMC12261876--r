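test_that("gating signal extraction reduces image series to the waveform", {
  arr <- makeNavigator(12, 60, 0.1, noiseSd = 0, asImages = TRUE)
  g <- extractGatingSignal(arr)
  u <- (1 - cos(2 * pi * 12 / 60 * timestamps(g))) / 2
  expect_gt(cor(amplitude(g), u), 0.9999)
  ## constant series -> constant amplitude
  const <- array(3, c(32, 32, 10))
  gc <- extractGatingSignal(const, times = seq(0, 0.9, 0.1))
  expect_true(all(abs(amplitude(gc) - 3) < 1e-12))
  ## single frame errors
  expect_error(extractGatingSignal(array(1, c(32, 32, 1))), ">= 2")
  expect_error(extractGatingSignal(arr, roi = matrix(FALSE, 32, 32)),
               "empty")
  ## polarity flag
  gi <- extractGatingSignal(GatingSeries(1:10, 1:10), invert = TRUE,
                            window = 1)
  expect_equal(amplitude(gi), -(1:10))
})

test_that("breathing frequency estimation is exact on a pure sinusoid", {
  t <- seq(0, 59.9, by = 0.1)
  g <- GatingSeries(t, sin(2 * pi * 0.25 * t))
  expect_equal(estimateBreathingFrequency(g), 15, tolerance = 1e-9)
  ## noisy synthetic navigator at 12/min over 480 s
  nav <- makeNavigator(12, 480, 0.1, noiseSd = 0.05, seed = 3)
  f <- estimateBreathingFrequency(extractGatingSignal(nav))
  expect_lt(abs(f - 12), 0.5)
  ## constant signal errors
  expect_error(estimateBreathingFrequency(GatingSeries(1:10, rep(1, 10))),
               "estimation error|flat")
})

test_that("frequency estimation is scale-free in time", {
  t <- seq(0, 299.9, by = 0.1)
  g <- GatingSeries(t, sin(2 * pi * 0.2 * t))  # 12/min
  f1 <- estimateBreathingFrequency(g)
  g2 <- GatingSeries(t * 2, sin(2 * pi * 0.2 * t))
  f2 <- estimateBreathingFrequency(g2)
  expect_equal(f2, f1 / 2, tolerance = 1e-9)
})

test_that("respiratory phase anchors troughs at 0 and peaks at 0.5", {
  t <- seq(0, 59.9, by = 0.1)
  a <- -cos(2 * pi * 0.25 * t)   # troughs at t = 0, 4, ...
  ph <- computeRespiratoryPhase(GatingSeries(t, a))
  isTrough <- abs(t / 4 - round(t / 4)) < 1e-9
  got <- ph$phase[ph$time %in% t[isTrough]]
  expect_true(all(pmin(got, 1 - got) < 1e-9))
  isPeak <- abs((t - 2) / 4 - round((t - 2) / 4)) < 1e-9
  gotP <- ph$phase[ph$time %in% t[isPeak]]
  expect_true(length(gotP) > 10 && all(abs(gotP - 0.5) < 1e-9))
  ## midpoint in time between an interior trough (t = 4) and the next
  ## peak (t = 6) -> 0.25 (linearity)
  mid <- ph$phase[which.min(abs(ph$time - 5))]
  expect_equal(mid, 0.25, tolerance = 1e-9)
  ## monotone modulo 1
  unwrapped <- ph$phase + cumsum(c(0, diff(ph$phase) < -0.5))
  expect_true(all(diff(unwrapped) > -1e-12))
  ## dropped samples flagged
  expect_true(all(attr(ph, "dropped") %in% seq_along(t)))
  expect_error(computeRespiratoryPhase(GatingSeries(1:10, rep(0, 10))),
               "flat|extrema")
})

test_that("bin assignment meets count, sharing and cap contracts", {
  ## 1000 uniform phases: 10 bins x 100 core, 20 shared (10 per neighbour)
  b <- assignBins((seq_len(1000) - 1) / 1000)
  expect_equal(b@nBins, 10L)
  expect_true(all(tabulate(b@coreBin, 10) == 100))
  expect_true(all(lengths(b@shared) == 20))
  ## cap: N = 2700 uniform -> 27 bins
  expect_equal(assignBins((seq_len(2700) - 1) / 2700)@nBins, 27L)
  ## too few acquisitions
  expect_error(assignBins(runif(99)), "binning error")
})

test_that("bin assignment invariants hold on random phase sets", {
  set.seed(42)
  for (rep in 1:5) {
    N <- sample(300:1500, 1)
    phases <- runif(N)
    b <- assignBins(phases)
    ## partition: every acquisition in exactly one core bin
    expect_equal(length(b@coreBin), N)
    expect_equal(sum(tabulate(b@coreBin, b@nBins)), N)
    ## occupancy after merging
    expect_true(all(tabulate(b@coreBin, b@nBins) >= 100))
    ## sharing locality: shared indices originate in a neighbouring bin
    for (bi in seq_len(b@nBins)) {
      donors <- unique(b@coreBin[b@shared[[bi]]])
      left <- if (bi == 1) b@nBins else bi - 1
      right <- if (bi == b@nBins) 1 else bi + 1
      expect_true(all(donors %in% c(left, right)))
    }
  }
})
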