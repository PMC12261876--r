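#' Scanner profile
#'
#' Describes one scanner as the generator sees it: its field strength and the
#' two knobs through which field strength acts on the ventilation-weighted
#' data, the parenchymal signal-to-noise ratio and a multiplier on the spatial
#' heterogeneity of the ventilation field. Higher field strength is modelled
#' as lower parenchymal SNR (rapid T2* decay at 3 T) together with more
#' heterogeneous raw ventilation-weighted values; no susceptibility physics is
#' simulated.
#'
#' @slot label Scanner label, e.g. "Center1-1.5T".
#' @slot fieldStrength Field strength in tesla.
#' @slot snr Ratio of mean parenchymal signal to noise standard deviation;
#'   \code{Inf} renders noise-free images.
#' @slot heterogeneityScale Multiplier on the spatial standard deviation of
#'   the specific-ventilation field (1 = reference).
#' @slot signalScale Arbitrary signal units of the noise-free parenchyma.
#' @export
setClass("ScannerProfile",
  representation(label = "character", fieldStrength = "numeric",
                 snr = "numeric", heterogeneityScale = "numeric",
                 signalScale = "numeric"),
  prototype(label = "scanner", fieldStrength = 1.5, snr = 100,
            heterogeneityScale = 1, signalScale = 100))

setValidity("ScannerProfile", function(object) {
  msg <- character(0)
  if (length(object@snr) != 1L || is.na(object@snr) || object@snr <= 0)
    msg <- c(msg, "snr must be a single positive value (Inf allowed)")
  if (object@heterogeneityScale < 0)
    msg <- c(msg, "heterogeneityScale must be >= 0")
  if (object@signalScale <= 0) msg <- c(msg, "signalScale must be > 0")
  if (object@fieldStrength <= 0) msg <- c(msg, "fieldStrength must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScannerProfile-class
#' @param label,fieldStrength,snr,heterogeneityScale,signalScale See slots.
#' @return A \code{ScannerProfile}.
#' @export
ScannerProfile <- function(label, fieldStrength = 1.5, snr = 100,
                           heterogeneityScale = 1, signalScale = 100) {
  new("ScannerProfile", label = label, fieldStrength = fieldStrength,
      snr = snr, heterogeneityScale = heterogeneityScale,
      signalScale = signalScale)
}

#' Subject specification for the synthetic cohort generator
#'
#' One simulated healthy volunteer: demographics plus the physiological and
#' geometric parameters that drive the forward model. Specific ventilation
#' (sv) is the fractional regional volume change per breath; regional
#' ventilation relates to it as RVent = sv/(1+sv) under the signal model.
#'
#' @slot subjectId Subject identifier.
#' @slot age Age in years (>= 18, healthy-volunteer inclusion).
#' @slot sex "F" or "M".
#' @slot center Center name.
#' @slot breathingFrequency Breaths per minute.
#' @slot tidalVolumeTarget Tidal volume in mL.
#' @slot lungSemiaxes Ellipsoid semiaxes of each lung in mm (x, y, z).
#' @slot svMean Mean specific ventilation inside the parenchyma.
#' @slot svCorrelationLength Correlation length of the sv field in mm.
#' @slot defectFraction Fraction of parenchyma rendered non-ventilated.
#' @slot seed Subject-level RNG seed.
#' @export
setClass("SubjectSpec",
  representation(subjectId = "character", age = "numeric", sex = "character",
                 center = "character", breathingFrequency = "numeric",
                 tidalVolumeTarget = "numeric", lungSemiaxes = "numeric",
                 svMean = "numeric", svCorrelationLength = "numeric",
                 defectFraction = "numeric", seed = "integer"))

setValidity("SubjectSpec", function(object) {
  msg <- character(0)
  if (object@age < 18) msg <- c(msg, "age must be >= 18")
  if (!object@sex %in% c("F", "M")) msg <- c(msg, "sex must be 'F' or 'M'")
  if (object@breathingFrequency <= 0)
    msg <- c(msg, "breathingFrequency must be > 0")
  if (object@tidalVolumeTarget <= 0)
    msg <- c(msg, "tidalVolumeTarget must be > 0")
  if (length(object@lungSemiaxes) != 3L || any(object@lungSemiaxes <= 0))
    msg <- c(msg, "lungSemiaxes must be three positive lengths (mm)")
  if (object@svMean < 0) msg <- c(msg, "svMean must be >= 0")
  if (object@defectFraction < 0 || object@defectFraction > 1)
    msg <- c(msg, "defectFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SubjectSpec-class
#' @param subjectId,age,sex,center,breathingFrequency,tidalVolumeTarget
#'   See slots.
#' @param lungSemiaxes,svMean,svCorrelationLength,defectFraction,seed
#'   See slots.
#' @return A \code{SubjectSpec}.
#' @export
SubjectSpec <- function(subjectId, age = 25, sex = "F", center = "Center1",
                        breathingFrequency = 12, tidalVolumeTarget = 450,
                        lungSemiaxes = c(50, 60, 95), svMean = 0.25,
                        svCorrelationLength = 30, defectFraction = 0,
                        seed = 1L) {
  new("SubjectSpec", subjectId = subjectId, age = age, sex = sex,
      center = center, breathingFrequency = breathingFrequency,
      tidalVolumeTarget = tidalVolumeTarget, lungSemiaxes = lungSemiaxes,
      svMean = svMean, svCorrelationLength = svCorrelationLength,
      defectFraction = defectFraction, seed = as.integer(seed))
}

#' Ground truth of one simulated measurement
#'
#' Holds the true per-voxel specific ventilation and regional ventilation
#' (RVent = sv/(1+sv)), the defect mask, the respiratory cycle waveform
#' (inflation fraction u(t) in [0,1] sampled at the navigator rate), and the
#' true tidal volume and breathing frequency, so recovery by the analysis
#' modules can be checked in closed form.
#'
#' @slot svField 3D array of specific ventilation.
#' @slot rventTrueField 3D array, \code{sv/(1+sv)} voxel-wise.
#' @slot defectMask Logical 3D array.
#' @slot cycleWaveform Numeric vector, u(t) in [0,1].
#' @slot trueTidalVolume mL.
#' @slot trueBreathingFrequency Breaths per minute.
#' @export
setClass("GroundTruth",
  representation(svField = "array", rventTrueField = "array",
                 defectMask = "array", cycleWaveform = "numeric",
                 trueTidalVolume = "numeric",
                 trueBreathingFrequency = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (any(object@svField < 0)) msg <- c(msg, "svField must be non-negative")
  expected <- object@svField / (1 + object@svField)
  if (max(abs(object@rventTrueField - expected)) > 1e-12)
    msg <- c(msg, "rventTrueField must equal svField/(1+svField)")
  u <- object@cycleWaveform
  ## sampled at the navigator rate, so the extremes are attained only up to
  ## the sampling grid
  if (length(u) && (min(u) > 0.01 || max(u) < 0.99))
    msg <- c(msg, "cycleWaveform must reach end-expiration (0) and end-inspiration (1)")
  if (length(msg)) msg else TRUE
})

#' Respiratory gating series
#'
#' A scalar respiratory amplitude over time, extracted from low-resolution
#' navigator images or simulated directly. Convention: higher amplitude means
#' more inflated (end-inspiration at peaks). For real data with the opposite
#' polarity, negate the amplitude (see \code{invert} in
#' \code{\link{extractGatingSignal}}).
#'
#' @slot timestamps Seconds, strictly increasing.
#' @slot amplitude Arbitrary units.
#' @export
setClass("GatingSeries",
  representation(timestamps = "numeric", amplitude = "numeric"))

setValidity("GatingSeries", function(object) {
  msg <- character(0)
  if (length(object@timestamps) < 2L) msg <- c(msg, "need >= 2 samples")
  if (length(object@timestamps) != length(object@amplitude))
    msg <- c(msg, "timestamps and amplitude lengths differ")
  if (any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(!is.finite(object@amplitude)))
    msg <- c(msg, "amplitude must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname GatingSeries-class
#' @param timestamps,amplitude See slots.
#' @return A \code{GatingSeries}.
#' @export
GatingSeries <- function(timestamps, amplitude) {
  new("GatingSeries", timestamps = as.numeric(timestamps),
      amplitude = as.numeric(amplitude))
}

#' Phase-resolved image series
#'
#' Registered signal volumes over one sorted respiratory cycle. All phases
#' live on the grid of the end-inspiratory reference (the registration
#' target), so the end-inspiration index doubles as the reference index.
#'
#' @slot data 4D array (x, y, z, phase), arbitrary signal units.
#' @slot voxelSize mm triple.
#' @slot expIdx Phase index of end-expiration.
#' @slot inspIdx Phase index of end-inspiration (= reference phase).
#' @slot phaseU Inflation fraction u of each phase, in [0, 1].
#' @export
setClass("PhaseResolvedImage",
  representation(data = "array", voxelSize = "numeric", expIdx = "integer",
                 inspIdx = "integer", phaseU = "numeric"))

setValidity("PhaseResolvedImage", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4D")
  else {
    np <- dim(object@data)[4L]
    if (np < 3L) msg <- c(msg, "need >= 3 respiratory phases")
    if (object@expIdx < 1L || object@expIdx > np ||
        object@inspIdx < 1L || object@inspIdx > np)
      msg <- c(msg, "phase indices out of range")
    if (object@expIdx == object@inspIdx)
      msg <- c(msg, "expIdx and inspIdx must differ")
    if (length(object@phaseU) != np)
      msg <- c(msg, "phaseU must have one value per phase")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' @rdname PhaseResolvedImage-class
#' @param data,voxelSize,expIdx,inspIdx,phaseU See slots.
#' @return A \code{PhaseResolvedImage}.
#' @export
PhaseResolvedImage <- function(data, voxelSize, expIdx, inspIdx,
                               phaseU = numeric(dim(data)[4L])) {
  new("PhaseResolvedImage", data = data, voxelSize = as.numeric(voxelSize),
      expIdx = as.integer(expIdx), inspIdx = as.integer(inspIdx),
      phaseU = as.numeric(phaseU))
}

#' One simulated free-breathing measurement
#'
#' Bundles the phase-resolved images, masks, navigator and ground truth of a
#' single scan of one subject on one scanner, plus provenance.
#'
#' @slot images A \code{PhaseResolvedImage}.
#' @slot parenchymaMask,vesselMask Logical 3D arrays; the vessel mask lies
#'   inside the parenchyma and is excluded from all statistics.
#' @slot inspMask,expMask End-inspiratory / end-expiratory lung masks used
#'   for tidal-volume estimation.
#' @slot navigator A \code{GatingSeries}.
#' @slot groundTruth A \code{GroundTruth}.
#' @slot subjectId,scanner Character provenance.
#' @slot measurementIndex 1 or 2.
#' @slot seed Measurement-level seed.
#' @export
setClass("SyntheticMeasurement",
  representation(images = "PhaseResolvedImage", parenchymaMask = "array",
                 vesselMask = "array", inspMask = "array", expMask = "array",
                 navigator = "GatingSeries", groundTruth = "GroundTruth",
                 subjectId = "character", scanner = "character",
                 measurementIndex = "integer", seed = "integer"))

setValidity("SyntheticMeasurement", function(object) {
  msg <- character(0)
  dg <- dim(object@images@data)[1:3]
  for (nm in c("parenchymaMask", "vesselMask", "inspMask", "expMask"))
    if (!identical(dim(slot(object, nm)), dg))
      msg <- c(msg, paste(nm, "grid differs from images"))
  if (any(object@vesselMask & !object@parenchymaMask))
    msg <- c(msg, "vesselMask must lie inside parenchymaMask")
  if (!object@measurementIndex %in% c(1L, 2L))
    msg <- c(msg, "measurementIndex must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Scalar ventilation parameters of one measurement
#'
#' The eight scalar parameters reported per measurement: mean and CoV of the
#' static RVent map, VVP based on RVent (threshold 40% of the in-mask 90th
#' percentile), mean and CoV of the FVL-CM map, VVP based on FVL-CM
#' (threshold 0.9), tidal volume, and breathing frequency.
#'
#' @slot meanRVent mL/mL.
#' @slot covRVent Percent.
#' @slot vvpRVent Percent.
#' @slot meanFVLCM Dimensionless in [-1, 1].
#' @slot covFVLCM Percent.
#' @slot vvpFVLCM Percent.
#' @slot tidalVolume mL.
#' @slot breathingFrequency Breaths per minute.
#' @export
setClass("VentilationSummary",
  representation(meanRVent = "numeric", covRVent = "numeric",
                 vvpRVent = "numeric", meanFVLCM = "numeric",
                 covFVLCM = "numeric", vvpFVLCM = "numeric",
                 tidalVolume = "numeric", breathingFrequency = "numeric"))

setValidity("VentilationSummary", function(object) {
  msg <- character(0)
  for (nm in c("vvpRVent", "vvpFVLCM")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 0 || v > 100))
      msg <- c(msg, paste(nm, "must lie in [0, 100]"))
  }
  for (nm in c("covRVent", "covFVLCM")) {
    v <- slot(object, nm)
    if (!is.na(v) && v < 0) msg <- c(msg, paste(nm, "must be >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' Respiratory bin assignment
#'
#' Result of sorting phased acquisitions into respiratory bins with a
#' minimum per-bin count and view sharing from the two cyclic neighbours.
#'
#' @slot nBins Number of bins after merging.
#' @slot coreBin Integer bin index per retained acquisition.
#' @slot shared List (one element per bin) of acquisition indices borrowed
#'   from the neighbouring bins.
#' @slot phaseEdges Phase boundaries of the bins in [0, 1]; bin i spans
#'   cyclically from \code{phaseEdges[i]} to \code{phaseEdges[i+1]}.
#' @slot phases Phase per retained acquisition.
#' @export
setClass("BinAssignment",
  representation(nBins = "integer", coreBin = "integer", shared = "list",
                 phaseEdges = "numeric", phases = "numeric"))

setValidity("BinAssignment", function(object) {
  msg <- character(0)
  if (length(object@coreBin) &&
      (min(object@coreBin) < 1L || max(object@coreBin) > object@nBins))
    msg <- c(msg, "coreBin indices out of range")
  if (length(object@shared) != object@nBins)
    msg <- c(msg, "shared must have one element per bin")
  if (length(msg)) msg else TRUE
})

## ---- accessors & show ------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("imgData", "PhaseResolvedImage", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSize", "PhaseResolvedImage", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "PhaseResolvedImage",
          function(x) prod(x@voxelSize))
#' @rdname accessors
#' @export
setMethod("nPhases", "PhaseResolvedImage", function(x) dim(x@data)[4L])
#' @rdname accessors
#' @export
setMethod("expIndex", "PhaseResolvedImage", function(x) x@expIdx)
#' @rdname accessors
#' @export
setMethod("inspIndex", "PhaseResolvedImage", function(x) x@inspIdx)
#' @rdname accessors
#' @export
setMethod("timestamps", "GatingSeries", function(x) x@timestamps)
#' @rdname accessors
#' @export
setMethod("amplitude", "GatingSeries", function(x) x@amplitude)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticMeasurement", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("parenchymaMask", "SyntheticMeasurement",
          function(x) x@parenchymaMask)
#' @rdname accessors
#' @export
setMethod("vesselMask", "SyntheticMeasurement", function(x) x@vesselMask)
#' @rdname accessors
#' @export
setMethod("navigator", "SyntheticMeasurement", function(x) x@navigator)

#' @rdname accessors
#' @details \code{analysisMask} is the mask all scalar statistics are taken
#'   over: parenchyma with the large-vessel voxels removed.
#' @export
setMethod("analysisMask", "SyntheticMeasurement",
          function(x) x@parenchymaMask & !x@vesselMask)

setMethod("show", "ScannerProfile", function(object) {
  cat(sprintf("ScannerProfile '%s': %.1f T, SNR %s, heterogeneity x%.2f\n",
              object@label, object@fieldStrength,
              format(object@snr), object@heterogeneityScale))
})

setMethod("show", "SubjectSpec", function(object) {
  cat(sprintf(
    "SubjectSpec %s (%s, %g y, %s): %g breaths/min, VT %g mL, sv %.3g\n",
    object@subjectId, object@sex, object@age, object@center,
    object@breathingFrequency, object@tidalVolumeTarget, object@svMean))
})

setMethod("show", "GatingSeries", function(object) {
  cat(sprintf("GatingSeries: %d samples over %.1f s\n",
              length(object@timestamps), diff(range(object@timestamps))))
})

setMethod("show", "PhaseResolvedImage", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "PhaseResolvedImage: %dx%dx%d voxels (%.3g mm3), %d phases (exp %d, insp/ref %d)\n",
    d[1], d[2], d[3], prod(object@voxelSize), d[4],
    object@expIdx, object@inspIdx))
})

setMethod("show", "SyntheticMeasurement", function(object) {
  cat(sprintf("SyntheticMeasurement: subject %s, scanner %s, measurement %d\n",
              object@subjectId, object@scanner, object@measurementIndex))
  show(object@images)
  cat(sprintf("  parenchyma %d voxels (%d vessel), true VT %.0f mL\n",
              sum(object@parenchymaMask), sum(object@vesselMask),
              object@groundTruth@trueTidalVolume))
})

setMethod("show", "VentilationSummary", function(object) {
  cat("VentilationSummary:\n")
  print(as(object, "data.frame"), row.names = FALSE)
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d bins, core counts %s, shared %s\n",
              object@nBins,
              paste(range(tabulate(object@coreBin, object@nBins)),
                    collapse = "-"),
              paste(range(lengths(object@shared)), collapse = "-")))
})

setAs("VentilationSummary", "data.frame", function(from)
  data.frame(meanRVent = from@meanRVent, covRVent = from@covRVent,
             vvpRVent = from@vvpRVent, meanFVLCM = from@meanFVLCM,
             covFVLCM = from@covFVLCM, vvpFVLCM = from@vvpFVLCM,
             tidalVolume = from@tidalVolume,
             breathingFrequency = from@breathingFrequency))

#' @export
#' @method as.data.frame VentilationSummary
#' @param x A \code{VentilationSummary}.
#' @param ... Unused.
#' @rdname VentilationSummary-class
as.data.frame.VentilationSummary <- function(x, ...) as(x, "data.frame")
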