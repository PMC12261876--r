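#' Render phase-resolved images from ground truth
#'
#' Forward signal model: inside the parenchyma, proton density is diluted by
#' local inflation, \code{S(x, p) = signalScale / (1 + sv(x) * u(p))}; outside
#' it the background is a constant \code{0.5 * signalScale}. The inflation
#' fraction u samples one full respiratory cycle on a raised-cosine shape,
#' rescaled to attain exactly 0 (end-expiration, phase 1) and 1
#' (end-inspiration). Additive zero-mean Gaussian noise has standard
#' deviation \code{mean in-mask noise-free signal / snr}; \code{snr = Inf}
#' renders deterministic noise-free images. Under this model the static
#' regional ventilation of a voxel is exactly \code{sv/(1+sv)}.
#'
#' @param gt List or \code{\linkS4class{GroundTruth}} providing
#'   \code{svField}.
#' @param masks Geometry list from \code{\link{makeLungGeometry}}.
#' @param nPhases Number of respiratory phases (>= 3).
#' @param profile A \code{\linkS4class{ScannerProfile}}.
#' @param voxelSize mm triple.
#' @param seed Integer seed for the noise substream.
#' @param lagField Optional 3D array of regional ventilation lags in cycle
#'   fractions: voxel inflation follows the raised-cosine cycle shifted by
#'   the local lag, emulating regionally delayed ventilation. With a lag
#'   field the per-voxel inflation is evaluated on the continuous cycle (it
#'   need not attain exactly 0 and 1 at the global end-expiration /
#'   end-inspiration phases).
#' @return A \code{\linkS4class{PhaseResolvedImage}}.
#' @export
renderPhaseImages <- function(gt, masks, nPhases, profile, voxelSize,
                              seed = 1L, lagField = NULL) {
  if (nPhases < 3L) stop("parameter error: nPhases must be >= 3")
  sv <- if (is(gt, "GroundTruth")) gt@svField else gt$svField
  dims <- dim(sv)
  u <- phaseInflation(nPhases)
  expIdx <- which.min(u)
  inspIdx <- which.max(u)
  scale <- profile@signalScale
  mask <- masks$parenchymaMask

  data <- array(0.5 * scale, c(dims, nPhases))
  idx <- which(mask)
  block <- prod(dims)
  if (is.null(lagField)) {
    for (p in seq_len(nPhases))
      data[idx + (p - 1L) * block] <- scale / (1 + sv[idx] * u[p])
  } else {
    lag <- lagField[idx]
    for (p in seq_len(nPhases)) {
      up <- (1 - cos(2 * pi * ((p - 1) / nPhases - lag))) / 2
      data[idx + (p - 1L) * block] <- scale / (1 + sv[idx] * up)
    }
  }

  if (is.finite(profile@snr)) {
    meanSignal <- mean(vapply(u, function(up)
      mean(scale / (1 + sv[idx] * up)), 0))
    sigma <- meanSignal / profile@snr
    data <- data + withSeed(seed, array(rnorm(length(data), sd = sigma),
                                        dim = dim(data)))
  }
  PhaseResolvedImage(data, voxelSize, expIdx, inspIdx, u)
}

## Inflation fraction of each phase over one cycle: raised cosine rescaled
## to hit exactly 0 and 1 for any nPhases >= 3.
phaseInflation <- function(nPhases) {
  u <- (1 - cos(2 * pi * (seq_len(nPhases) - 1) / nPhases)) / 2
  (u - min(u)) / (max(u) - min(u))
}

#' Simulate a respiratory navigator series
#'
#' Produces the scalar gating amplitude a low-resolution (32 x 32, 100 ms)
#' navigator would yield: the inflation waveform plus Gaussian noise, higher
#' amplitude meaning more inflated.
#'
#' @param frequency Breathing frequency, breaths per minute.
#' @param duration Seconds (should span several cycles).
#' @param dt Sampling interval in seconds (default 0.1).
#' @param noiseSd Noise standard deviation in waveform units (waveform spans
#'   0 to 1).
#' @param seed Integer seed.
#' @param asImages If \code{TRUE}, return a 32 x 32 x T array (the waveform
#'   broadcast over a smooth spatial weighting plus per-pixel noise) with the
#'   timestamps as attribute \code{"timestamps"}, for exercising gating-signal
#'   extraction from image series.
#' @return A \code{\linkS4class{GatingSeries}}, or an array if
#'   \code{asImages}.
#' @export
makeNavigator <- function(frequency, duration, dt = 0.1, noiseSd = 0.05,
                          seed = 1L, asImages = FALSE) {
  if (dt <= 0) stop("parameter error: dt must be > 0")
  if (duration < 2 * 60 / frequency)
    stop("parameter error: duration must span several breathing cycles")
  t <- seq(0, duration - dt, by = dt)
  u <- (1 - cos(2 * pi * frequency / 60 * t)) / 2
  if (asImages) {
    w <- outer(dnorm(seq(-2, 2, length.out = 32)),
               dnorm(seq(-2, 2, length.out = 32)))
    w <- w / max(w)
    arr <- withSeed(seed, {
      a <- outer(as.vector(w), u)
      if (noiseSd > 0) a <- a + rnorm(length(a), sd = noiseSd)
      array(a, c(32, 32, length(t)))
    })
    attr(arr, "timestamps") <- t
    return(arr)
  }
  a <- if (noiseSd > 0)
    u + withSeed(seed, rnorm(length(t), sd = noiseSd)) else u
  GatingSeries(t, a)
}
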