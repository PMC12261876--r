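#' Sample a ground-truth specific-ventilation field
#'
#' Draws a spatially smooth random specific-ventilation (sv) field inside the
#' parenchyma: Gaussian white noise smoothed to the requested correlation
#' length, standardised in-mask, then scaled to mean \code{svMean} and
#' standard deviation \code{0.30 * svMean * heterogeneityScale} and clipped at
#' zero. The 0.30 relative spread at heterogeneity 1 places the map
#' coefficient of variation of RVent near the ~30\% reported for healthy
#' lungs. A \code{defectFraction} > 0 zeroes sv inside the lowest-valued
#' contiguous region of a second smooth field. The true regional ventilation
#' follows as \code{RVent = sv/(1+sv)}.
#'
#' @param spec A \code{\linkS4class{SubjectSpec}}.
#' @param profile A \code{\linkS4class{ScannerProfile}}.
#' @param parenchymaMask Logical 3D array.
#' @param voxelSize mm triple.
#' @param seed Integer seed for the field substream; defaults to the
#'   subject's seed.
#' @return A list with \code{svField}, \code{rventTrueField} (3D arrays) and
#'   \code{defectMask} (logical 3D array).
#' @export
sampleVentilationField <- function(spec, profile, parenchymaMask, voxelSize,
                                   seed = spec@seed) {
  if (spec@svMean < 0) stop("parameter error: svMean must be >= 0")
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  dims <- dim(parenchymaMask)
  inm <- which(parenchymaMask)
  sigmaVox <- spec@svCorrelationLength / voxelSize
  sdTarget <- 0.30 * spec@svMean * profile@heterogeneityScale

  sv <- array(spec@svMean, dims)
  defect <- array(FALSE, dims)
  withSeed(seed, {
    if (sdTarget > 0) {
      z <- gaussianSmooth3D(array(rnorm(prod(dims)), dims), sigmaVox)
      z <- (z - mean(z[inm])) / sdPop(z[inm])
      sv <- spec@svMean + sdTarget * z
      sv[sv < 0] <- 0
    }
    if (spec@defectFraction > 0) {
      w <- gaussianSmooth3D(array(rnorm(prod(dims)), dims), sigmaVox)
      thr <- quantile(w[inm], spec@defectFraction, type = 7)
      defect[inm] <- w[inm] <= thr
      sv[defect] <- 0
    }
  })
  sv[!parenchymaMask] <- 0
  list(svField = sv, rventTrueField = sv / (1 + sv),
       defectMask = defect & parenchymaMask)
}
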