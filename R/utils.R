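#' @importFrom methods new validObject is slot show
#' @importFrom stats dnorm rnorm runif quantile sd var median cor pnorm
#'   psignrank approx
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

#' Derive a reproducible integer seed for a named substream
#'
#' All randomness in a study run flows from one root seed; per-subject and
#' per-measurement draws use seeds derived from the root and a path of name
#' components, so regenerating any one measurement does not depend on the
#' order in which others were generated.
#'
#' @param root Integer root seed.
#' @param ... Character or numeric path components naming the substream.
#' @return An integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(root, ...) {
  parts <- paste(c(as.character(root), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483562
  as.integer(h + 1L)
}

## Evaluate expr with a local RNG state seeded at `seed`; the caller's
## .Random.seed is untouched.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
## Truncated kernels are renormalised at the edges so a constant array is
## a fixed point of the filter.
gaussianSmooth3D <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3L)
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    ## axes are rotated each pass so the active axis is always first
    if (sigma[ax] > 0) {
      n <- dim(x)[1L]
      half <- max(1L, ceiling(3 * sigma[ax]))
      k <- dnorm(seq(-half, half), sd = sigma[ax])
      K <- matrix(0, n, n)
      for (i in seq_len(n)) {
        j <- (i - half):(i + half)
        ok <- j >= 1L & j <= n
        K[i, j[ok]] <- k[ok]
      }
      K <- K / rowSums(K)
      d <- dim(x)
      x <- K %*% matrix(x, nrow = d[1L])
      dim(x) <- d
    }
    x <- aperm(x, c(2, 3, 1))
  }
  x
}

## Local maxima filtered by topographic prominence and a minimum time
## separation. Returns indices into x, ordered by time.
findProminentPeaks <- function(x, times, minProminence, minSeparation) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[1:i]
    j <- which(left > x[i])
    lo1 <- if (length(j)) min(left[max(j):i]) else min(left)
    right <- x[i:n]
    j <- which(right > x[i])
    lo2 <- if (length(j)) min(right[1:min(j)]) else min(right)
    x[i] - max(lo1, lo2)
  }, 0)
  cand <- cand[prom >= minProminence]
  if (!length(cand)) return(integer(0))
  ## greedy: keep the highest peaks, enforce the separation
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(times[i] - times[keep]) >= minSeparation))
      keep <- c(keep, i)
  }
  sort(keep)
}

## Short stable hash of an R object (config manifests): polynomial rolling
## hash over the deparsed representation, kept inside 31 bits.
hashConfig <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Population (1/n) standard deviation.
sdPop <- function(x) sqrt(mean((x - mean(x))^2))
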