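#' Extract a respiratory gating signal
#'
#' Reduces a low-resolution navigator image series to a scalar respiratory
#' amplitude: the spatial mean over a region of interest (default: the
#' central half-field) followed by moving-average smoothing. A scalar series
#' (\code{\linkS4class{GatingSeries}}) passes through the smoothing only.
#'
#' @param x A 3D array (px, py, time) with timestamps in attribute
#'   \code{"timestamps"} (or supplied via \code{times}), or a
#'   \code{GatingSeries}.
#' @param roi Optional logical matrix selecting navigator pixels; default is
#'   the central half-field.
#' @param window Moving-average window in samples (odd; default 3). Edge
#'   samples without a full window are trimmed.
#' @param invert Negate the amplitude (for navigators whose raw polarity is
#'   inspiration-down); the pipeline convention is higher amplitude =
#'   more inflated.
#' @param times Timestamps for array input, if not carried as an attribute.
#' @return A \code{\linkS4class{GatingSeries}}.
#' @export
extractGatingSignal <- function(x, roi = NULL, window = 3L, invert = FALSE,
                                times = NULL) {
  if (is(x, "GatingSeries")) {
    t <- timestamps(x); a <- amplitude(x)
  } else {
    d <- dim(x)
    if (is.null(d) || length(d) != 3L)
      stop("navigator input must be a (px, py, time) array or GatingSeries")
    if (d[3] < 2L) stop("navigator series needs >= 2 frames")
    if (is.null(roi)) {
      roi <- matrix(FALSE, d[1], d[2])
      qx <- seq.int(floor(d[1] / 4) + 1L, ceiling(3 * d[1] / 4))
      qy <- seq.int(floor(d[2] / 4) + 1L, ceiling(3 * d[2] / 4))
      roi[qx, qy] <- TRUE
    }
    if (!any(roi)) stop("empty navigator roi")
    flat <- matrix(x, prod(d[1:2]), d[3])
    a <- colMeans(flat[as.vector(roi), , drop = FALSE])
    t <- attr(x, "timestamps") %||% times
    if (is.null(t)) t <- seq(0, by = 0.1, length.out = d[3])
  }
  if (invert) a <- -a
  window <- as.integer(window)
  if (window > 1L) {
    if (window %% 2L == 0L) window <- window + 1L
    if (length(a) <= window) stop("series too short for smoothing window")
    sm <- stats::filter(a, rep(1 / window, window), sides = 2)
    keep <- !is.na(sm)
    t <- t[keep]; a <- as.numeric(sm[keep])
  }
  GatingSeries(t, a)
}

#' Estimate breathing frequency from a gating series
#'
#' Counts detected end-inspiration peaks and converts the mean peak-to-peak
#' interval to breaths per minute: \code{(nPeaks - 1) / spanned time * 60}.
#' Peaks are local maxima with topographic prominence of at least
#' \code{promFactor} times the amplitude interquartile range and at least
#' \code{minSeparation} seconds apart.
#'
#' @param g A \code{\linkS4class{GatingSeries}}.
#' @param promFactor Prominence threshold as a fraction of the amplitude IQR
#'   (default 0.2).
#' @param minSeparation Minimum peak separation in seconds (default 1.5).
#' @return Breathing frequency in breaths per minute.
#' @examples
#' t <- seq(0, 59.9, by = 0.1)
#' estimateBreathingFrequency(GatingSeries(t, sin(2 * pi * 0.25 * t)))  # 15
#' @export
estimateBreathingFrequency <- function(g, promFactor = 0.2,
                                       minSeparation = 1.5) {
  a <- amplitude(g); t <- timestamps(g)
  prom <- promFactor * diff(quantile(a, c(0.25, 0.75), names = FALSE))
  if (prom <= 0) stop("estimation error: flat gating signal")
  peaks <- findProminentPeaks(a, t, prom, minSeparation)
  if (length(peaks) < 2L)
    stop("estimation error: fewer than 2 breathing peaks detected")
  (length(peaks) - 1) / (t[peaks[length(peaks)]] - t[peaks[1]]) * 60
}

#' Compute respiratory phase
#'
#' Assigns each retained sample a respiratory phase in [0, 1): 0 at detected
#' troughs (end-expiration), 0.5 at peaks (end-inspiration),
#' piecewise-linear in time within each half-cycle. Samples before the first
#' and after the last detected extremum have no defined phase and are
#' dropped; their indices are reported.
#'
#' @inheritParams estimateBreathingFrequency
#' @return A data.frame with columns \code{index}, \code{time},
#'   \code{phase}, plus attribute \code{"dropped"} holding the indices of
#'   unphased samples.
#' @export
computeRespiratoryPhase <- function(g, promFactor = 0.2,
                                    minSeparation = 1.5) {
  a <- amplitude(g); t <- timestamps(g)
  iqr <- diff(quantile(a, c(0.25, 0.75), names = FALSE))
  if (iqr <= 0) stop("phase error: no extrema in a flat signal")
  prom <- promFactor * iqr
  peaks <- findProminentPeaks(a, t, prom, minSeparation)
  troughs <- findProminentPeaks(-a, t, prom, minSeparation)
  ext <- data.frame(index = c(peaks, troughs),
                    kind = rep(c("peak", "trough"),
                               c(length(peaks), length(troughs))))
  ext <- ext[order(ext$index), ]
  ## enforce alternation: of consecutive same-kind extrema keep the extreme one
  keep <- rep(TRUE, nrow(ext))
  i <- 1L
  while (i < nrow(ext)) {
    j <- i + 1L
    while (j <= nrow(ext) && !keep[j]) j <- j + 1L
    if (j > nrow(ext)) break
    if (ext$kind[i] == ext$kind[j]) {
      vi <- a[ext$index[i]]; vj <- a[ext$index[j]]
      better <- if (ext$kind[i] == "peak") vj > vi else vj < vi
      if (better) { keep[i] <- FALSE; i <- j } else keep[j] <- FALSE
    } else i <- j
  }
  ext <- ext[keep, ]
  if (nrow(ext) < 2L) stop("phase error: fewer than 2 extrema detected")

  ## cumulative phase: troughs at integers, peaks at integers + 0.5
  cum <- numeric(nrow(ext))
  cum[1] <- if (ext$kind[1] == "trough") 0 else 0.5
  for (k in 2:nrow(ext)) cum[k] <- cum[k - 1] + 0.5
  tx <- t[ext$index]
  inside <- which(t >= tx[1] & t <= tx[length(tx)])
  phase <- stats::approx(tx, cum, xout = t[inside])$y %% 1
  dropped <- setdiff(seq_along(t), inside)
  out <- data.frame(index = inside, time = t[inside], phase = phase)
  attr(out, "dropped") <- dropped
  out
}

#' Assign phased acquisitions to respiratory bins
#'
#' Sorts acquisitions into equal-width cyclic phase bins, merges adjacent
#' bins until every core count reaches \code{minCount}, and then lets each
#' bin borrow its nearest-in-phase neighbours' acquisitions as view sharing:
#' \code{floor(shareFraction * core count / 2)} from each of the two cyclic
#' neighbour bins.
#'
#' @param phases Numeric vector of phases in [0, 1).
#' @param minCount Minimum acquisitions per bin (default 100).
#' @param shareFraction View-sharing fraction of the core count borrowed
#'   from the neighbours (default 0.2).
#' @param nBins Number of bins; default \code{floor(N / minCount)} capped at
#'   \code{maxBins} and floored at 1.
#' @param maxBins Cap on the bin count (default 51).
#' @return A \code{\linkS4class{BinAssignment}}.
#' @examples
#' b <- assignBins((seq_len(1000) - 1) / 1000)
#' b  # 10 bins, 100 core + 20 shared each
#' @export
assignBins <- function(phases, minCount = 100L, shareFraction = 0.2,
                       nBins = NULL, maxBins = 51L) {
  N <- length(phases)
  if (N < minCount)
    stop("binning error: fewer acquisitions (", N, ") than minCount")
  if (any(phases < 0 | phases >= 1)) stop("phases must lie in [0, 1)")
  if (is.null(nBins)) nBins <- max(1L, min(maxBins, N %/% minCount))
  nBins0 <- as.integer(nBins)

  base <- pmin(floor(phases * nBins0) + 1L, nBins0)  # base interval per acq
  binOf <- seq_len(nBins0)                           # base interval -> bin id
  repeat {
    counts <- tabulate(binOf[base], max(binOf))
    counts <- counts[sort(unique(binOf))]
    ids <- sort(unique(binOf))
    if (length(ids) == 1L || all(counts >= minCount)) break
    under <- ids[counts < minCount]
    b <- under[which.min(counts[match(under, ids)])]
    pos <- which(ids == b)
    left <- ids[if (pos == 1L) length(ids) else pos - 1L]
    right <- ids[if (pos == length(ids)) 1L else pos + 1L]
    cl <- counts[match(left, ids)]; cr <- counts[match(right, ids)]
    into <- if (cl < cr) left else if (cr < cl) right else min(left, right)
    binOf[binOf == b] <- into
  }
  ids <- sort(unique(binOf))
  core <- match(binOf[base], ids)
  nb <- length(ids)

  ## bin phase edges: boundaries of base intervals where the bin id changes
  edges0 <- (0:nBins0) / nBins0
  changes <- which(binOf != c(binOf[-1], binOf[1]))
  phaseEdges <- if (nb == 1L) c(0, 1) else sort(edges0[changes %% nBins0 + 1])

  ## view sharing: borrow nearest-in-phase acquisitions from both neighbours
  shared <- vector("list", nb)
  for (bi in seq_len(nb)) {
    m <- floor(shareFraction * sum(core == bi) / 2)
    if (m == 0 || nb < 2L) { shared[[bi]] <- integer(0); next }
    leftBin <- if (bi == 1L) nb else bi - 1L
    rightBin <- if (bi == nb) 1L else bi + 1L
    take <- integer(0)
    myIntervals <- which(binOf == ids[bi])
    for (donor in unique(c(leftBin, rightBin))) {
      cand <- which(core == donor)
      ## nearest in cyclic phase to this bin's phase span
      dmin <- vapply(phases[cand], function(p)
        cyclicDistToBin(p, myIntervals, nBins0), 0)
      take <- c(take, cand[order(dmin)][seq_len(min(m, length(cand)))])
    }
    shared[[bi]] <- sort(unique(take))
  }
  new("BinAssignment", nBins = nb, coreBin = as.integer(core),
      shared = shared, phaseEdges = phaseEdges, phases = as.numeric(phases))
}

## cyclic distance from phase p to the union of base intervals of a bin
cyclicDistToBin <- function(p, intervals, nBins0) {
  lo <- (intervals - 1) / nBins0
  hi <- intervals / nBins0
  inside <- any(p >= lo & p < hi)
  if (inside) return(0)
  d <- pmin(cyclicDist(p, lo), cyclicDist(p, hi))
  min(d)
}

cyclicDist <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 1 - d)
}
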