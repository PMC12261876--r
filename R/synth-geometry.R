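#' Build synthetic lung geometry
#'
#' Constructs two ellipsoidal lungs with a branching vessel tree on a regular
#' voxel grid, standing in for the segmentation masks a deep-learning model
#' would supply for real data. The end-expiratory lung is the ellipsoid pair
#' itself; the end-inspiratory lung adds exactly the number of shell voxels
#' needed to realise the requested tidal volume, so
#' \code{(insp - exp) voxels * voxel volume} matches \code{tidalVolumeTarget}
#' to within one voxel volume by construction. The parenchyma mask equals the
#' end-inspiratory lung (images are registered to end-inspiration).
#'
#' @param spec A \code{\linkS4class{SubjectSpec}}.
#' @param gridDim Integer triple of voxel counts per axis (>= 16 each).
#' @param voxelSize mm triple.
#' @param tidalVolume Tidal volume to realise in mL; defaults to the spec's
#'   target (overridden when a perturbation scales the cycle amplitude).
#' @return A list with logical arrays \code{parenchymaMask},
#'   \code{vesselMask}, \code{inspMask}, \code{expMask}.
#' @examples
#' spec <- SubjectSpec("S1", lungSemiaxes = c(50, 60, 95))
#' g <- makeLungGeometry(spec, c(24, 24, 24), c(10, 10, 10))
#' sum(g$inspMask) - sum(g$expMask)  # = round(450 / 1.0) voxels
#' @export
makeLungGeometry <- function(spec, gridDim, voxelSize,
                             tidalVolume = spec@tidalVolumeTarget) {
  gridDim <- as.integer(gridDim)
  if (length(gridDim) != 3L || any(gridDim < 16L))
    stop("geometry error: grid dimensions must be >= 16 per axis")
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  ax <- spec@lungSemiaxes
  if (any(ax <= 0)) stop("geometry error: lung semiaxes must be positive")

  ## physical coordinates, grid centred at the origin
  co <- lapply(1:3, function(i)
    (seq_len(gridDim[i]) - (gridDim[i] + 1) / 2) * voxelSize[i])
  extent <- gridDim * voxelSize
  gap <- 0.15 * ax[1]                      # mediastinal gap
  centers <- list(c(-(ax[1] + gap), 0, 0), c(ax[1] + gap, 0, 0))
  for (cc in centers)
    if (any(abs(cc) + ax > extent / 2))
      stop("geometry error: lung semiaxes exceed the grid")

  ## normalised ellipsoid radius: r <= 1 is the end-expiratory lung
  r <- array(Inf, gridDim)
  X <- co[[1]]; Y <- co[[2]]; Z <- co[[3]]
  for (cc in centers) {
    rx <- ((X - cc[1]) / ax[1])^2
    ry <- ((Y - cc[2]) / ax[2])^2
    rz <- ((Z - cc[3]) / ax[3])^2
    rl <- sqrt(outer(outer(rx, ry, "+"), rz, "+"))
    r <- pmin(r, rl)
  }
  expMask <- r <= 1

  nAdd <- round(tidalVolume * 1000 / prod(voxelSize))  # mL -> mm3 -> voxels
  outside <- which(!expMask)
  if (length(outside) < nAdd)
    stop("geometry error: grid too small for the requested tidal volume")
  shell <- outside[order(r[outside])][seq_len(nAdd)]
  inspMask <- expMask
  inspMask[shell] <- TRUE

  ## vessel tree: a vertical trunk plus one oblique branch per lung,
  ## clipped to the end-expiratory lung so it sits inside all phases
  vessel <- array(FALSE, gridDim)
  for (cc in centers) {
    rx <- ((X - cc[1]) / (0.16 * ax[1]))^2
    ry <- ((Y - cc[2]) / (0.16 * ax[2]))^2
    trunk <- outer(sqrt(outer(rx, ry, "+")) <= 1,
                   abs(Z - cc[3]) <= 0.55 * ax[3], "&")
    vessel <- vessel | trunk
    ## oblique branch: offset tube in x drifting with z
    for (s in c(-1, 1)) {
      xoff <- outer(X - cc[1], Z - cc[3],
                    function(x, z) x - s * 0.5 * (z / ax[3]) * ax[1])
      branch <- array(FALSE, gridDim)
      for (k in seq_along(Z)) {
        inx <- (xoff[, k] / (0.10 * ax[1]))^2
        iny <- ((Y - cc[2]) / (0.10 * ax[2]))^2
        branch[, , k] <- outer(inx, iny, "+") <= 1 &
          abs(Z[k] - cc[3]) <= 0.45 * ax[3]
      }
      vessel <- vessel | branch
    }
  }
  vessel <- vessel & expMask

  list(parenchymaMask = inspMask, vesselMask = vessel,
       inspMask = inspMask, expMask = expMask)
}
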