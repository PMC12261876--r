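#' Simulate one free-breathing measurement
#'
#' Builds geometry, ground-truth ventilation, phase-resolved images and a
#' navigator series for one subject on one scanner. Repeat (second)
#' measurements may carry a habituation perturbation: \code{tidalFactor}
#' scales the respiratory cycle amplitude — and with it the effective
#' specific ventilation and tidal volume — and \code{frequencyFactor} scales
#' the breathing frequency. The ground truth is updated consistently, so a
#' \code{tidalFactor} of 0.85 lowers the true mean RVent by close to 15%
#' (exactly \code{mean(sv*0.85/(1+sv*0.85))} vs \code{mean(sv/(1+sv))}).
#'
#' The subject's spatial ventilation pattern is drawn from a subject-level
#' seed substream shared across scanners and measurements, so repeated and
#' cross-scanner measurements of the same subject see the same lungs; only
#' the noise (and any perturbation) differs between measurements.
#'
#' @param spec A \code{\linkS4class{SubjectSpec}}.
#' @param profile A \code{\linkS4class{ScannerProfile}}.
#' @param measurementIndex 1 or 2; the perturbation applies to measurement 2.
#' @param perturbation List with \code{tidalFactor} and
#'   \code{frequencyFactor} (both > 0, default 1).
#' @param gridDim,voxelSize Voxel grid descriptor.
#' @param nPhases Number of respiratory phases.
#' @param navDuration,navDt,navNoiseSd Navigator settings (seconds, seconds,
#'   waveform units); navigator noise is suppressed for \code{snr = Inf}
#'   profiles.
#' @param physiology Between-measurement physiological variability: a list
#'   with \code{amp_sd} (log-sd of a global breathing-amplitude factor that
#'   scales effective sv and tidal volume together), \code{spatial_sd}
#'   (log-sd of a smooth spatial modulation of the sv field — the
#'   ventilation distribution is not identical between scans),
#'   \code{lag_sd} (median sd, in cycle fractions, of a smooth regional
#'   ventilation-lag field: parts of the lung inflate slightly out of phase,
#'   which is what the FVL-CM metric is sensitive to), \code{lag_logsd}
#'   (log-sd of the per-measurement lag amplitude — breathing regularity
#'   differs between scans, which dominates the between-measurement
#'   variability of FVL-CM-based ventilated volume) and
#'   \code{freq_sd} (log-sd of a breathing-frequency factor). Defaults are
#'   calibrated to the between-measurement coefficients of variation
#'   reported for repeated healthy-volunteer scans. Suppressed entirely for
#'   \code{snr = Inf} profiles, which define the deterministic ideal-phantom
#'   condition.
#' @return A \code{\linkS4class{SyntheticMeasurement}}.
#' @export
simulateMeasurement <- function(spec, profile, measurementIndex = 1L,
                                perturbation = list(tidalFactor = 1,
                                                    frequencyFactor = 1),
                                gridDim = c(24, 24, 24),
                                voxelSize = c(10, 10, 10), nPhases = 12L,
                                navDuration = 60, navDt = 0.1,
                                navNoiseSd = 0.05,
                                physiology = list(amp_sd = 0.10,
                                                  spatial_sd = 0.14,
                                                  lag_sd = 0.03,
                                                  lag_logsd = 0.25,
                                                  freq_sd = 0.05)) {
  tf <- perturbation$tidalFactor %||% 1
  ff <- perturbation$frequencyFactor %||% 1
  if (tf <= 0 || ff <= 0)
    stop("parameter error: perturbation factors must be > 0")
  if (measurementIndex == 1L) tf <- ff <- 1

  ## measurement-level physiological state (identical machinery for both
  ## measurements; only the substream differs)
  ideal <- !is.finite(profile@snr)
  phys <- list(amp = 1, freq = 1, mod = NULL)
  if (!ideal) {
    physSeed <- deriveSeed(spec@seed, profile@label, measurementIndex,
                           "physio")
    phys <- withSeed(physSeed, {
      amp <- exp(rnorm(1, 0, physiology$amp_sd %||% 0.10))
      fq <- exp(rnorm(1, 0, physiology$freq_sd %||% 0.05))
      list(amp = amp, freq = fq, sd = physiology$spatial_sd %||% 0.14,
           lagSd = (physiology$lag_sd %||% 0.03) *
             exp(rnorm(1, 0, physiology$lag_logsd %||% 0.25)),
           seed = deriveSeed(physSeed, "spatial"),
           lagSeed = deriveSeed(physSeed, "lag"))
    })
  }

  tidal <- spec@tidalVolumeTarget * tf * phys$amp
  freq <- spec@breathingFrequency * ff * phys$freq
  geo <- makeLungGeometry(spec, gridDim, voxelSize, tidalVolume = tidal)

  fieldSeed <- deriveSeed(spec@seed, "field")
  field <- sampleVentilationField(spec, profile, geo$parenchymaMask,
                                  voxelSize, seed = fieldSeed)
  svEff <- field$svField * tf * phys$amp
  if (!ideal && phys$sd > 0) {
    sigmaVox <- spec@svCorrelationLength / rep_len(voxelSize, 3)
    eps <- withSeed(phys$seed,
                    gaussianSmooth3D(array(rnorm(prod(gridDim)), gridDim),
                                     sigmaVox))
    inm <- which(geo$parenchymaMask)
    eps <- (eps - mean(eps[inm])) / sdPop(eps[inm]) * phys$sd
    svEff <- svEff * exp(eps)
    svEff[!geo$parenchymaMask] <- 0
  }
  lagField <- NULL
  if (!ideal && phys$lagSd > 0) {
    sigmaVox <- spec@svCorrelationLength / rep_len(voxelSize, 3)
    lagField <- withSeed(phys$lagSeed,
                         gaussianSmooth3D(array(rnorm(prod(gridDim)),
                                                gridDim), sigmaVox))
    inm <- which(geo$parenchymaMask)
    lagField <- (lagField - mean(lagField[inm])) / sdPop(lagField[inm]) *
      phys$lagSd
  }
  nav <- makeNavigator(freq, navDuration, navDt,
                       noiseSd = if (is.finite(profile@snr)) navNoiseSd else 0,
                       seed = deriveSeed(spec@seed, profile@label,
                                         measurementIndex, "nav"))
  gt <- new("GroundTruth", svField = svEff,
            rventTrueField = svEff / (1 + svEff),
            defectMask = field$defectMask,
            cycleWaveform = (1 - cos(2 * pi * freq / 60 *
                                       timestamps(nav))) / 2,
            trueTidalVolume = tidal, trueBreathingFrequency = freq)
  img <- renderPhaseImages(gt, geo, nPhases, profile, voxelSize,
                           seed = deriveSeed(spec@seed, profile@label,
                                             measurementIndex, "noise"),
                           lagField = lagField)
  new("SyntheticMeasurement", images = img,
      parenchymaMask = geo$parenchymaMask, vesselMask = geo$vesselMask,
      inspMask = geo$inspMask, expMask = geo$expMask, navigator = nav,
      groundTruth = gt, subjectId = spec@subjectId, scanner = profile@label,
      measurementIndex = as.integer(measurementIndex),
      seed = deriveSeed(spec@seed, profile@label, measurementIndex))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the subject specifications of a study cohort
#'
#' Samples demographics and physiological parameters for every subject of
#' every configured center, from the configured ranges, using per-center
#' substreams of the root seed.
#'
#' @param config Study configuration list (see
#'   \code{\link{defaultStudyConfig}}).
#' @return Named list of \code{\linkS4class{SubjectSpec}} objects.
#' @export
cohortSubjects <- function(config) {
  subjects <- list()
  for (ctr in config$centers) {
    dem <- modifyList(config$demographics, ctr$demographics %||% list())
    seed <- deriveSeed(config$seed, "cohort", ctr$name)
    n <- ctr$n
    if (n == 0) next
    draws <- withSeed(seed, list(
      age = runif(n, dem$age_range[1], dem$age_range[2]),
      sex = ifelse(runif(n) < dem$female_fraction, "F", "M"),
      bf = runif(n, dem$bf_range[1], dem$bf_range[2]),
      tv = runif(n, dem$tv_range[1], dem$tv_range[2]),
      sv = runif(n, dem$sv_mean_range[1], dem$sv_mean_range[2])))
    for (i in seq_len(n)) {
      id <- sprintf("%s-S%02d", ctr$name, i)
      if (id %in% names(subjects))
        stop("config error: duplicate subject id ", id)
      subjects[[id]] <- SubjectSpec(
        subjectId = id, age = draws$age[i], sex = draws$sex[i],
        center = ctr$name, breathingFrequency = draws$bf[i],
        tidalVolumeTarget = draws$tv[i],
        lungSemiaxes = dem$lung_semiaxes, svMean = draws$sv[i],
        svCorrelationLength = dem$sv_correlation_length,
        defectFraction = dem$defect_fraction,
        seed = deriveSeed(config$seed, "subject", id))
    }
  }
  subjects
}

#' Generate a full synthetic cohort
#'
#' Simulates the study design: every subject of every center receives two
#' measurements on each scanner profile assigned to their center (e.g.
#' Center 1 on both a 1.5-T and a 3-T profile, Center 2 on one 3-T profile).
#' The second measurement carries the configured perturbation.
#'
#' @param config Study configuration list (see
#'   \code{\link{defaultStudyConfig}}).
#' @return List with \code{measurements} (list of
#'   \code{\linkS4class{SyntheticMeasurement}}), \code{cohort} (data.frame of
#'   provenance and demographics, one row per measurement) and
#'   \code{subjects}.
#' @examples
#' cfg <- defaultStudyConfig(n1 = 1, n2 = 1)
#' cohort <- generateCohort(cfg)
#' nrow(cohort$cohort)  # 1*2*2 + 1*1*2 = 6 measurements
#' @export
generateCohort <- function(config) {
  subjects <- cohortSubjects(config)
  profiles <- studyProfiles(config)
  measurements <- list()
  rows <- list()
  for (ctr in config$centers) {
    for (sub in subjects) {
      if (sub@center != ctr$name) next
      for (plab in ctr$profiles) {
        for (m in 1:2) {
          meas <- simulateMeasurement(
            sub, profiles[[plab]], measurementIndex = m,
            perturbation = config$perturbation,
            gridDim = config$grid$dim, voxelSize = config$grid$voxel_size,
            nPhases = config$n_phases,
            navDuration = config$navigator$duration,
            navDt = config$navigator$dt,
            navNoiseSd = config$navigator$noise_sd,
            physiology = config$physiology %||% list())
          key <- sprintf("%s_%s_m%d", sub@subjectId, plab, m)
          measurements[[key]] <- meas
          rows[[key]] <- data.frame(
            subject_id = sub@subjectId, age = sub@age, sex = sub@sex,
            center = ctr$name, scanner = plab,
            field_strength = profiles[[plab]]@fieldStrength,
            measurement = m, seed = meas@seed)
        }
      }
    }
  }
  list(measurements = measurements,
       cohort = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       subjects = subjects)
}

## profile list keyed by label
studyProfiles <- function(config) {
  out <- list()
  for (p in config$profiles)
    out[[p$label]] <- ScannerProfile(p$label, p$field_strength, p$snr,
                                     p$heterogeneity_scale,
                                     p$signal_scale %||% 100)
  for (ctr in config$centers)
    for (plab in ctr$profiles)
      if (is.null(out[[plab]]))
        stop("config error: profile '", plab, "' is not defined")
  out
}
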