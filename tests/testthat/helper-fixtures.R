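## Small shared fixtures, built in code.

## grid small enough for fast tests, large enough for stable statistics
smallGrid <- function() list(dim = c(16L, 16L, 16L), voxel = c(10, 10, 10))

smallSpec <- function(svMean = 0.25, tidal = 350, seed = 7L, ...)
  SubjectSpec("T1", breathingFrequency = 12, tidalVolumeTarget = tidal,
              lungSemiaxes = c(32, 38, 56), svMean = svMean, seed = seed, ...)

noiseFreeProfile <- function(het = 0)
  ScannerProfile("ideal", snr = Inf, heterogeneityScale = het)

noisyProfile <- function(snr = 100, het = 1)
  ScannerProfile("noisy", snr = snr, heterogeneityScale = het)

noiseFreeMeasurement <- function(svMean = 0.25, het = 0, nPhases = 8,
                                 tidal = 350, m = 1L,
                                 perturbation = list(tidalFactor = 1,
                                                     frequencyFactor = 1)) {
  g <- smallGrid()
  simulateMeasurement(smallSpec(svMean = svMean, tidal = tidal),
                      noiseFreeProfile(het), measurementIndex = m,
                      perturbation = perturbation, gridDim = g$dim,
                      voxelSize = g$voxel, nPhases = nPhases)
}

## study config scaled for test runtime: 16^3 grid, 8 phases
testStudyConfig <- function(n1 = 3, n2 = 3, seed = 11, snrOverride = NULL) {
  cfg <- defaultStudyConfig(n1 = n1, n2 = n2, seed = seed,
                            gridDim = c(16, 16, 16), nPhases = 8)
  cfg$demographics$lung_semiaxes <- c(32, 38, 56)
  cfg$demographics$tv_range <- c(280, 450)
  if (!is.null(snrOverride))
    cfg$profiles <- lapply(cfg$profiles, function(p) {
      p$snr <- snrOverride
      p
    })
  cfg
}

## habituation scenario: one 3-T center, second measurement with scaled
## cycle amplitude
habituationConfig <- function(n = 26, seed = 1, tidalFactor = 0.85) {
  cfg <- testStudyConfig(n1 = 0, n2 = n, seed = seed)
  cfg$centers <- list(list(name = "Center2", n = n,
                           profiles = "Center2-3T"))
  cfg$perturbation <- list(tidalFactor = tidalFactor, frequencyFactor = 1)
  cfg
}

## field-strength scenario: one center on both profiles
fieldStrengthConfig <- function(n = 6, seed = 1) {
  cfg <- testStudyConfig(n1 = n, n2 = 0, seed = seed)
  cfg$centers <- list(list(name = "Center1", n = n,
                           profiles = c("Center1-1.5T", "Center1-3T")))
  cfg
}
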