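test_that("lung geometry realises the requested tidal volume exactly", {
  spec <- smallSpec(tidal = 400)
  g <- makeLungGeometry(spec, c(16, 16, 16), c(10, 10, 10))
  expect_gt(sum(g$parenchymaMask), 0)
  expect_gt(sum(g$vesselMask), 0)
  expect_false(any(g$vesselMask & !g$parenchymaMask))
  expect_true(all(g$inspMask[g$expMask]))  # insp contains exp
  ## 400 mL at 1000 mm3 voxels -> 400 voxels
  expect_equal(sum(g$inspMask) - sum(g$expMask), 400)
})

test_that("tidal-volume voxel count matches at 8 mm3 voxels", {
  ## 400 mL at 8 mm3 -> 50,000 voxels, within one voxel
  spec <- SubjectSpec("big", tidalVolumeTarget = 400,
                      lungSemiaxes = c(50, 60, 95))
  g <- makeLungGeometry(spec, c(112, 112, 112), c(2, 2, 2))
  dn <- sum(g$inspMask) - sum(g$expMask)
  expect_lte(abs(dn - 50000), 1)
  tv <- tidalVolume(g$inspMask, g$expMask, c(2, 2, 2))
  expect_equal(as.numeric(tv), 400, tolerance = 1e-6)
})

test_that("degenerate or oversized geometry errors", {
  expect_error(SubjectSpec("bad", lungSemiaxes = c(0, 0, 0)), "positive")
  spec <- smallSpec()
  expect_error(makeLungGeometry(spec, c(8, 8, 8), c(10, 10, 10)),
               "geometry error")
  big <- SubjectSpec("big", lungSemiaxes = c(500, 500, 500))
  expect_error(makeLungGeometry(big, c(16, 16, 16), c(10, 10, 10)),
               "geometry error")
})

test_that("ventilation field honours mean, heterogeneity and determinism", {
  spec <- smallSpec(svMean = 0.25)
  g <- makeLungGeometry(spec, c(16, 16, 16), c(10, 10, 10))
  ## zero-variance limit: constant field
  f0 <- sampleVentilationField(spec, noiseFreeProfile(0), g$parenchymaMask,
                               c(10, 10, 10))
  expect_true(all(abs(f0$svField[g$parenchymaMask] - 0.25) < 1e-12))
  expect_true(all(abs(f0$rventTrueField[g$parenchymaMask] - 0.2) < 1e-12))
  ## determinism
  f1 <- sampleVentilationField(spec, noisyProfile(), g$parenchymaMask,
                               c(10, 10, 10), seed = 5)
  f2 <- sampleVentilationField(spec, noisyProfile(), g$parenchymaMask,
                               c(10, 10, 10), seed = 5)
  expect_identical(f1$svField, f2$svField)
  f3 <- sampleVentilationField(spec, noisyProfile(), g$parenchymaMask,
                               c(10, 10, 10), seed = 6)
  expect_false(identical(f1$svField, f3$svField))
})

test_that("heterogeneity scale monotonically increases true RVent CoV", {
  spec <- smallSpec(svMean = 0.25)
  g <- makeLungGeometry(spec, c(16, 16, 16), c(10, 10, 10))
  mask <- g$parenchymaMask
  covs <- sapply(c(0.5, 1, 1.5, 2), function(h) {
    cc <- sapply(1:5, function(s) {
      f <- sampleVentilationField(spec, noisyProfile(het = h), mask,
                                  c(10, 10, 10), seed = s)
      v <- f$rventTrueField[mask]
      sd(v) / mean(v)
    })
    mean(cc)
  })
  expect_true(all(diff(covs) > 0))
})

test_that("signal model matches its closed form", {
  ## single-voxel closed form: sv = 0.25, u in {0, 1} -> S_exp/S_insp = 1.25
  m <- noiseFreeMeasurement(svMean = 0.25)
  img <- m@images
  idx <- which(analysisMask(m))[1]
  d <- dim(imgData(img))
  block <- prod(d[1:3])
  sExp <- imgData(img)[idx + (expIndex(img) - 1) * block]
  sInsp <- imgData(img)[idx + (inspIndex(img) - 1) * block]
  expect_equal(sExp / sInsp, 1.25, tolerance = 1e-12)
  ## sv = 0 -> all phases identical
  m0 <- noiseFreeMeasurement(svMean = 0)
  a <- imgData(m0@images)
  expect_true(all(abs(a - as.vector(a[, , , 1])) < 1e-12))
  ## determinism of the noise-free render
  m2 <- noiseFreeMeasurement(svMean = 0.25)
  expect_identical(imgData(m@images), imgData(m2@images))
})

test_that("navigator series has the right shape, length and noise limit", {
  nav <- makeNavigator(15, 60, 0.1, noiseSd = 0)
  expect_equal(length(timestamps(nav)), 600)
  ## noise 0: equals the waveform exactly
  u <- (1 - cos(2 * pi * 15 / 60 * timestamps(nav))) / 2
  expect_equal(amplitude(nav), u)
  ## 15 cycles in 60 s at 15/min
  expect_equal(estimateBreathingFrequency(nav), 15, tolerance = 1e-6)
  expect_equal(length(timestamps(makeNavigator(12, 480, 0.1))), 4800)
  expect_error(makeNavigator(12, 60, dt = 0), "parameter error")
})

test_that("habituation perturbation scales ground truth consistently", {
  m1 <- noiseFreeMeasurement(svMean = 0.25, m = 1,
                             perturbation = list(tidalFactor = 0.85,
                                                 frequencyFactor = 0.9))
  m2 <- noiseFreeMeasurement(svMean = 0.25, m = 2,
                             perturbation = list(tidalFactor = 0.85,
                                                 frequencyFactor = 0.9))
  gt1 <- groundTruth(m1); gt2 <- groundTruth(m2)
  ## closed form: sv*0.85/(1+sv*0.85) vs sv/(1+sv)
  expect_equal(mean(gt2@rventTrueField[analysisMask(m2)]),
               0.25 * 0.85 / (1 + 0.25 * 0.85), tolerance = 1e-9)
  rel <- mean(gt2@rventTrueField[analysisMask(m2)]) /
    mean(gt1@rventTrueField[analysisMask(m1)])
  expect_equal(rel, (0.2125 / 1.2125) / 0.2, tolerance = 1e-9)
  expect_equal(gt2@trueBreathingFrequency, 12 * 0.9)
  expect_equal(gt2@trueTidalVolume, 350 * 0.85)
  ## tidal consistency invariant: mask difference matches true VT
  tv <- tidalVolume(m2@inspMask, m2@expMask, c(10, 10, 10))
  expect_lte(abs(as.numeric(tv) - gt2@trueTidalVolume), 1)
  expect_error(noiseFreeMeasurement(m = 2,
                                    perturbation = list(tidalFactor = -1)),
               "parameter error")
})

test_that("cohort generation mirrors the two-center design", {
  cfg <- testStudyConfig(n1 = 2, n2 = 1)
  cfg$n_phases <- 3
  cohort <- generateCohort(cfg)
  ## n1 subjects x 2 profiles x 2 + n2 x 1 profile x 2
  expect_equal(nrow(cohort$cohort), 2 * 4 + 1 * 2)
  expect_equal(length(cohort$measurements), nrow(cohort$cohort))
  expect_setequal(unique(cohort$cohort$center), c("Center1", "Center2"))
  ## determinism of the cohort table
  cohort2 <- generateCohort(cfg)
  expect_identical(cohort$cohort, cohort2$cohort)
  ## empty Center-1 block is valid
  cfg0 <- testStudyConfig(n1 = 0, n2 = 1)
  cfg0$n_phases <- 3
  expect_equal(nrow(generateCohort(cfg0)$cohort), 2)
  ## demographics within configured ranges
  ages <- cohort$cohort$age
  expect_true(all(ages >= 18 & ages <= 65))
})

test_that("noise-free recovery: mapped mean RVent equals ground truth", {
  m <- noiseFreeMeasurement(svMean = 0.25, het = 1)
  s <- summarizeMeasurement(m)
  truth <- mean(groundTruth(m)@rventTrueField[analysisMask(m)])
  expect_lt(abs(s@meanRVent - truth), 1e-9)
})
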