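#' Compute the regional ventilation cycle
#'
#' Voxel-wise regional ventilation for every respiratory phase,
#' \deqn{RVent(x, p) = S_{Ref}(x)/S_p(x) - S_{Ref}(x)/S_{Exp}(x),}
#' where the reference phase is end-inspiration (the registration target).
#' At end-expiration RVent is identically zero; the static RVent map is the
#' cycle at end-inspiration, which reduces to \code{1 - S_Insp/S_Exp}.
#'
#' @param img A \code{\linkS4class{PhaseResolvedImage}}.
#' @param mask Logical 3D array; signal must be strictly positive in-mask at
#'   every phase.
#' @return A list with \code{cycle} (4D array, in-mask values, 0 elsewhere)
#'   and \code{static} (3D array, the end-inspiration map).
#' @export
computeRVentCycle <- function(img, mask) {
  d <- dim(img@data)
  if (!identical(dim(mask), d[1:3])) stop("mask grid differs from images")
  idx <- which(mask)
  np <- d[4]
  block <- prod(d[1:3])
  bad <- 0L
  for (p in seq_len(np))
    bad <- bad + sum(img@data[idx + (p - 1L) * block] <= 0)
  if (bad > 0)
    stop("data error: non-positive in-mask signal at ", bad,
         " voxel-phase samples")
  sRef <- img@data[idx + (img@inspIdx - 1L) * block]
  sExp <- img@data[idx + (img@expIdx - 1L) * block]
  cyc <- array(0, d)
  for (p in seq_len(np)) {
    sp <- img@data[idx + (p - 1L) * block]
    cyc[idx + (p - 1L) * block] <- sRef / sp - sRef / sExp
  }
  static <- array(0, d[1:3])
  static[idx] <- cyc[idx + (img@inspIdx - 1L) * block]
  list(cycle = cyc, static = static, expIdx = img@expIdx,
       inspIdx = img@inspIdx)
}

#' Summarise a parameter map over a mask
#'
#' In-mask mean and coefficient of variation (percent). The map CoV uses the
#' population (1/n) standard deviation; the sample form is available via
#' \code{sdType}.
#'
#' @param map 3D array.
#' @param mask Logical 3D array, nonempty.
#' @param sdType "population" (default) or "sample".
#' @return Named numeric vector \code{c(mean, cov)} with \code{cov} in
#'   percent.
#' @export
summarizeMap <- function(map, mask, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  v <- map[mask]
  if (!length(v)) stop("empty mask")
  m <- mean(v)
  s <- if (sdType == "population") sdPop(v) else sd(v)
  if (m == 0) {
    if (s > 0) stop("CoV undefined: zero mean with nonzero sd")
    return(c(mean = 0, cov = 0))
  }
  c(mean = m, cov = 100 * s / m)
}

#' Ventilated volume percentage from an RVent map
#'
#' Thresholds the static RVent map at 40\% of its in-mask 90th percentile
#' (linear-interpolation percentile); voxels strictly above the threshold
#' count as ventilated.
#'
#' @param staticMap 3D array of static RVent.
#' @param mask Logical 3D array, nonempty.
#' @param thresholdFraction Fraction of the 90th percentile (default 0.4).
#' @param percentile Percentile defining the reference level (default 0.9).
#' @return List with \code{vvp} (percent), \code{threshold}, and \code{map}
#'   (logical 3D ventilated-volume map; FALSE marks defect voxels in-mask).
#' @export
vvpRVent <- function(staticMap, mask, thresholdFraction = 0.4,
                     percentile = 0.9) {
  v <- staticMap[mask]
  if (!length(v)) stop("empty mask")
  thr <- thresholdFraction * quantile(v, percentile, names = FALSE, type = 7)
  vv <- array(FALSE, dim(staticMap))
  vv[mask] <- v > thr
  list(vvp = 100 * mean(v > thr), threshold = thr, map = vv)
}

#' Build per-voxel flow-volume loops
#'
#' For every in-mask voxel: the volume samples are the RVent values over the
#' cyclic phase order starting at end-expiration, and the flow samples are
#' the central cyclic difference of the volume with respect to phase index.
#' The reference loop is the voxel-wise mean loop over the mask. Cyclic flow
#' sums to zero, so every loop is closed.
#'
#' @param rvent Result of \code{\link{computeRVentCycle}} (or a 4D cycle
#'   array).
#' @param mask Logical 3D array.
#' @param expIdx End-expiration phase index (taken from the cycle list when
#'   present).
#' @return List with \code{volume} and \code{flow} (matrices, voxels x
#'   phases), \code{refVolume}, \code{refFlow}, and \code{voxels} (in-mask
#'   indices).
#' @export
buildFVL <- function(rvent, mask, expIdx = NULL) {
  cyc <- if (is.list(rvent)) rvent$cycle else rvent
  d <- dim(cyc)
  np <- d[4]
  if (np < 3L) stop("need >= 3 phases for flow-volume loops")
  idx <- which(mask)
  block <- prod(d[1:3])
  vol <- vapply(seq_len(np), function(p) cyc[idx + (p - 1L) * block],
                numeric(length(idx)))
  if (is.null(expIdx)) {
    if (is.list(rvent) && !is.null(rvent$expIdx)) expIdx <- rvent$expIdx
    else stop("expIdx is required when the cycle is passed as a bare array")
  }
  ord <- ((expIdx - 1L + seq_len(np) - 1L) %% np) + 1L
  vol <- vol[, ord, drop = FALSE]
  nxt <- c(2:np, 1L); prv <- c(np, 1:(np - 1L))
  flow <- (vol[, nxt, drop = FALSE] - vol[, prv, drop = FALSE]) / 2
  list(volume = vol, flow = flow, refVolume = colMeans(vol),
       refFlow = colMeans(flow), voxels = idx)
}

#' Flow-volume-loop cross-correlation metric map
#'
#' Correlates each voxel's flow-volume loop with the reference loop at zero
#' lag: volume and flow sample vectors are standardised separately,
#' concatenated, and compared by Pearson correlation, clipped to [-1, 1].
#' Voxels whose loop has zero variance get FVL-CM 0 and are flagged.
#'
#' @param fvls Result of \code{\link{buildFVL}}.
#' @param mask Logical 3D array (defines the output grid).
#' @return List with \code{map} (3D array, 0 outside the mask),
#'   \code{flagged} (indices of zero-variance voxels).
#' @export
fvlCorrelationMap <- function(fvls, mask) {
  refV <- standardizeLoop(fvls$refVolume)
  refF <- standardizeLoop(fvls$refFlow)
  if (is.null(refV) || is.null(refF)) {
    ## degenerate (e.g. zero-ventilation) data: no reference dynamics to
    ## correlate against, so every voxel is flagged with FVL-CM 0
    warning("reference loop has zero variance; FVL-CM set to 0")
    map <- array(0, dim(mask))
    return(list(map = map, flagged = fvls$voxels))
  }
  ref <- c(refV, refF)
  ## standardising volume and flow separately gives every concatenated
  ## vector zero mean and unit scale, so the Pearson correlation with the
  ## reference reduces to one matrix product
  stdRows <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowMeans(m * m) - mu * mu)
    list(x = (m - mu) / s, zero = s == 0)
  }
  vol <- stdRows(fvls$volume)
  flw <- stdRows(fvls$flow)
  bad <- vol$zero | flw$zero
  vals <- as.vector(cbind(vol$x, flw$x) %*% ref) / length(ref)
  vals <- pmin(1, pmax(-1, vals))
  vals[bad] <- 0
  map <- array(0, dim(mask))
  map[fvls$voxels] <- vals
  list(map = map, flagged = fvls$voxels[which(bad)])
}

standardizeLoop <- function(x) {
  s <- sdPop(x)
  if (s == 0) return(NULL)
  (x - mean(x)) / s
}

#' Ventilated volume percentage from an FVL-CM map
#'
#' Voxels with FVL-CM strictly above the fixed threshold 0.9 count as
#' ventilated.
#'
#' @param fvlcmMap 3D array of FVL-CM values.
#' @param mask Logical 3D array, nonempty.
#' @param threshold Fixed threshold (default 0.9).
#' @return List with \code{vvp} (percent) and \code{map} (logical 3D
#'   ventilated-volume map).
#' @export
vvpFVLCM <- function(fvlcmMap, mask, threshold = 0.9) {
  v <- fvlcmMap[mask]
  if (!length(v)) stop("empty mask")
  vv <- array(FALSE, dim(fvlcmMap))
  vv[mask] <- v > threshold
  list(vvp = 100 * mean(v > threshold), map = vv)
}

#' Tidal volume from morphological masks
#'
#' Lung volume difference between the end-inspiratory and end-expiratory
#' masks, in mL. A negative value (expiratory mask larger) is returned with
#' a warning flag attribute.
#'
#' @param inspMask,expMask Logical 3D arrays on a shared grid.
#' @param voxelSize mm triple.
#' @return Tidal volume in mL; attribute \code{"inverted"} is TRUE when
#'   negative.
#' @export
tidalVolume <- function(inspMask, expMask, voxelSize) {
  if (!identical(dim(inspMask), dim(expMask)))
    stop("masks must share a grid")
  tv <- (sum(inspMask) - sum(expMask)) * prod(voxelSize) / 1000
  if (tv < 0) {
    warning("tidal volume is negative: inspiratory mask smaller than ",
            "expiratory mask")
    attr(tv, "inverted") <- TRUE
  }
  tv
}

#' Summarise one measurement into its scalar ventilation parameters
#'
#' Runs the full per-measurement analysis: RVent cycle and static map,
#' flow-volume loops and FVL-CM map, both ventilated-volume percentages,
#' tidal volume from the morphological masks, and breathing frequency from
#' the navigator. All map statistics are taken over the parenchyma mask with
#' vessel voxels removed.
#'
#' @param meas A \code{\linkS4class{SyntheticMeasurement}} (or any object
#'   with the same slots).
#' @param keepMaps Also return the static RVent map, FVL-CM map and both
#'   binary ventilated-volume maps (needed for spatial-overlap analyses).
#' @return A \code{\linkS4class{VentilationSummary}}, or a list
#'   \code{(summary, maps)} if \code{keepMaps}.
#' @export
summarizeMeasurement <- function(meas, keepMaps = FALSE) {
  mask <- analysisMask(meas)
  rv <- computeRVentCycle(meas@images, mask)
  rvStats <- summarizeMap(rv$static, mask)
  vvpR <- vvpRVent(rv$static, mask)
  fvls <- buildFVL(rv, mask, expIdx = expIndex(meas@images))
  cm <- fvlCorrelationMap(fvls, mask)
  cmStats <- summarizeMap(cm$map, mask)
  vvpF <- vvpFVLCM(cm$map, mask)
  tv <- tidalVolume(meas@inspMask, meas@expMask, voxelSize(meas@images))
  bf <- estimateBreathingFrequency(extractGatingSignal(navigator(meas)))
  summary <- new("VentilationSummary",
                 meanRVent = unname(rvStats["mean"]),
                 covRVent = unname(rvStats["cov"]),
                 vvpRVent = vvpR$vvp,
                 meanFVLCM = unname(cmStats["mean"]),
                 covFVLCM = unname(cmStats["cov"]),
                 vvpFVLCM = vvpF$vvp,
                 tidalVolume = as.numeric(tv), breathingFrequency = bf)
  if (!keepMaps) return(summary)
  list(summary = summary,
       maps = list(rventStatic = rv$static, fvlcm = cm$map,
                   vvRVent = vvpR$map, vvFVLCM = vvpF$map, mask = mask))
}
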