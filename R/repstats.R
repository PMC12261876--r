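#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95\% limits of agreement,
#' \code{bias +/- 1.96 * sd(differences)} (sample sd), for paired values.
#' Differences are taken as condition A minus condition B.
#'
#' @param x1,x2 Paired numeric vectors (condition A, condition B).
#' @return List with \code{bias}, \code{sdDiff}, \code{loaLow},
#'   \code{loaHigh}, \code{n}.
#' @examples
#' blandAltman(c(10, 12, 14), c(10, 10, 10))
#' @export
blandAltman <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  if (length(x1) < 2L) stop("need at least 2 pairs")
  d <- x1 - x2
  bias <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  if (is.na(s)) s <- 0
  list(bias = bias, sdDiff = s, loaLow = bias - 1.96 * s,
       loaHigh = bias + 1.96 * s, n = length(d))
}

#' Between-measurement coefficient of variation
#'
#' Per subject, the CoV of the two paired values,
#' \code{100 * sd(x1, x2) / mean(x1, x2)}, where the two-value sample sd is
#' \code{|x1 - x2| / sqrt(2)}; the cohort summary is the median over
#' subjects. Subjects with zero mean are flagged and excluded from the
#' median.
#'
#' @param x1,x2 Paired numeric vectors.
#' @return List with \code{perSubject} (percent; NA where flagged),
#'   \code{median} (percent), \code{flagged} (indices with zero mean).
#' @export
pairwiseCoV <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  m <- (x1 + x2) / 2
  s <- abs(x1 - x2) / sqrt(2)
  cov <- ifelse(m == 0, NA_real_, 100 * s / m)
  flagged <- which(m == 0)
  list(perSubject = cov, median = median(cov, na.rm = TRUE),
       flagged = flagged)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) for paired measurements, from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with subjects as random rows (\code{MS_R}), measurements as random
#' columns (\code{MS_C}), residual \code{MS_E}, k = 2 conditions;
#' single-measurement, absolute-agreement form.
#'
#' @param x1,x2 Paired numeric vectors, length >= 3.
#' @return The ICC value.
#' @export
iccAbsoluteAgreement <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  n <- length(x1)
  if (n < 3L) stop("need at least 3 subjects for ICC")
  X <- cbind(x1, x2)
  k <- 2L
  if (max(X) == min(X)) stop("ICC undefined: all values identical")
  gm <- mean(X)
  rowm <- rowMeans(X)
  colm <- colMeans(X)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sst <- sum((X - gm)^2)
  mse <- (sst - k * sum((rowm - gm)^2) - n * sum((colm - gm)^2)) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Interpret an ICC value (Viera-Garrett scale)
#'
#' @param icc ICC value (<= 1).
#' @return Character label: "less than chance" (<= 0), "slight" (0, 0.20],
#'   "fair" (0.20, 0.40], "moderate" (0.40, 0.60], "substantial"
#'   (0.60, 0.80], "almost perfect" (0.80, 1].
#' @examples
#' interpretICC(0.35)  # "fair"
#' @export
interpretICC <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc > 1) stop("ICC cannot exceed 1")
  if (icc <= 0) "less than chance"
  else if (icc <= 0.20) "slight"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's d for paired measurements
#'
#' Standardised mean difference using the standard deviation of the paired
#' differences (d_z form), \code{mean(x1 - x2) / sd(x1 - x2)}. With the
#' \code{"average"} denominator the pooled standard deviation of the two
#' conditions is used instead. All-zero differences give d = 0.
#'
#' @param x1,x2 Paired numeric vectors.
#' @param denominator "differences" (default) or "average".
#' @return Cohen's d.
#' @export
cohensDPaired <- function(x1, x2, denominator = c("differences", "average")) {
  denominator <- match.arg(denominator)
  stopifnot(length(x1) == length(x2))
  d <- x1 - x2
  if (all(d == 0)) return(0)
  s <- if (denominator == "differences") sd(d)
       else sqrt((var(x1) + var(x2)) / 2)
  if (is.na(s) || s == 0)
    stop("effect size undefined: zero variability with nonzero difference")
  mean(d) / s
}

#' Interpret an effect size (Sawilowsky scale)
#'
#' Labels |d| by the largest threshold it reaches: very small (0.01), small
#' (0.2), medium (0.5), large (0.8), very large (1.2), huge (2.0); below
#' 0.01 the effect is "negligible".
#'
#' @param d Cohen's d (sign is ignored).
#' @return Character label.
#' @examples
#' interpretEffectSize(0.5)   # "medium"
#' interpretEffectSize(-1.3)  # "very large"
#' @export
interpretEffectSize <- function(d) {
  if (is.na(d)) return(NA_character_)
  a <- abs(d)
  thresholds <- c(0.01, 0.2, 0.5, 0.8, 1.2, 2.0)
  labels <- c("very small", "small", "medium", "large", "very large", "huge")
  if (a < thresholds[1]) return("negligible")
  labels[max(which(a >= thresholds))]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired differences. Zero differences are
#' dropped before ranking (flagged in the result); absolute differences are
#' midranked. The null distribution is exact — via the signed-rank
#' distribution when there are no ties, or full enumeration of all sign
#' patterns when there are — for n up to \code{exactMax}; above that a
#' normal approximation with tie correction and continuity correction is
#' used. All differences zero gives p = 1 with a flag.
#'
#' @param x1,x2 Paired numeric vectors, or \code{x2} missing and \code{x1}
#'   the differences.
#' @param exactMax Largest n for which the exact distribution is used
#'   (default 25; enumeration is used for tied data up to n = 16).
#' @return List with \code{p}, \code{statistic} (W+ of condition A), \code{n}
#'   (nonzero differences), \code{allZero} flag and \code{method}.
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4), c(1, 1, 1))$p  # 0.25
#' @export
wilcoxonSignedRank <- function(x1, x2 = NULL, exactMax = 25L) {
  d <- if (is.null(x2)) x1 else x1 - x2
  if (!length(d)) stop("no differences supplied")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = 0, n = 0L, allZero = TRUE,
                method = "all differences zero"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  eps <- 1e-9
  if (!ties && n <= exactMax) {
    pl <- psignrank(W, n)
    pg <- psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact signed-rank distribution"
  } else if (n <= 16L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    pl <- mean(Wall <= W + eps)
    pg <- mean(Wall >= W - eps)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact sign-pattern enumeration"
  } else {
    ew <- n * (n + 1) / 4
    tieTab <- table(r)
    varw <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (W - ew - 0.5 * sign(W - ew)) / sqrt(varw)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(p = p, statistic = W, n = n, allZero = FALSE, method = method,
       zerosDropped = zeros)
}

#' Spatial overlap of two binary ventilated-volume maps
#'
#' Percentage of matching voxel labels between two binary maps within a
#' mask:
#' \deqn{Overlap = \frac{2 (n_{vv} + n_{dd})}{n_{v1} + n_{v2} + n_{d1} + n_{d2}} \times 100,}
#' where \eqn{n_{vv}} voxels are ventilated in both maps, \eqn{n_{dd}}
#' defect in both, and \eqn{n_{vi}}, \eqn{n_{di}} are the per-map ventilated
#' and defect counts.
#'
#' @param vv1,vv2 Logical arrays (TRUE = ventilated).
#' @param mask Logical array restricting the comparison; nonempty.
#' @return Overlap percentage in [0, 100].
#' @export
spatialOverlap <- function(vv1, vv2, mask) {
  if (!identical(dim(vv1), dim(vv2))) stop("maps must share a grid")
  m <- which(mask)
  if (!length(m)) stop("empty mask")
  a <- vv1[m]; b <- vv2[m]
  nvv <- sum(a & b); ndd <- sum(!a & !b)
  denom <- sum(a) + sum(b) + sum(!a) + sum(!b)
  2 * (nvv + ndd) / denom * 100
}

#' Age-match two cohorts
#'
#' One-to-one matching of subjects between two cohorts minimising the total
#' absolute age difference (optimal assignment; solved by an
#' order-preserving dynamic program on the sorted ages, which is optimal for
#' absolute-difference costs). The \code{min(nA, nB)} pairs are returned;
#' unmatched subjects of the larger cohort are listed as excluded.
#'
#' @param agesA,agesB Numeric ages.
#' @param idsA,idsB Subject identifiers (default positional).
#' @return List with \code{pairs} (data.frame idA, idB, ageA, ageB,
#'   absDiff), \code{excluded} (ids), \code{medianAbsDiff},
#'   \code{totalAbsDiff}.
#' @export
ageMatch <- function(agesA, agesB, idsA = paste0("A", seq_along(agesA)),
                     idsB = paste0("B", seq_along(agesB))) {
  if (!length(agesA) || !length(agesB)) stop("both cohorts must be nonempty")
  swapped <- length(agesA) > length(agesB)
  if (swapped) {
    tmp <- list(agesA, idsA); agesA <- agesB; idsA <- idsB
    agesB <- tmp[[1]]; idsB <- tmp[[2]]
  }
  oa <- order(agesA); ob <- order(agesB)
  a <- agesA[oa]; b <- agesB[ob]
  n <- length(a); m <- length(b)
  ## dp[i+1, j+1]: min cost matching first i of a within first j of b
  dp <- matrix(Inf, n + 1, m + 1)
  dp[1, ] <- 0
  for (i in seq_len(n))
    for (j in i:m)
      dp[i + 1, j + 1] <- min(dp[i + 1, j],
                              dp[i, j] + abs(a[i] - b[j]))
  ## backtrack
  match_j <- integer(n)
  i <- n; j <- m
  while (i > 0) {
    if (j > i && dp[i + 1, j + 1] == dp[i + 1, j]) j <- j - 1
    else { match_j[i] <- j; i <- i - 1; j <- j - 1 }
  }
  pairs <- data.frame(
    idA = idsA[oa], idB = idsB[ob][match_j],
    ageA = a, ageB = b[match_j], absDiff = abs(a - b[match_j]),
    stringsAsFactors = FALSE)
  if (swapped)
    pairs <- data.frame(idA = pairs$idB, idB = pairs$idA, ageA = pairs$ageB,
                        ageB = pairs$ageA, absDiff = pairs$absDiff,
                        stringsAsFactors = FALSE)
  excluded <- setdiff(idsB, pairs[[if (swapped) "idA" else "idB"]])
  list(pairs = pairs, excluded = excluded,
       medianAbsDiff = median(pairs$absDiff),
       totalAbsDiff = sum(pairs$absDiff))
}

#' Percent change of a comparison mean against a reference mean
#'
#' \code{100 * (comparison - reference) / reference}; the reference is the
#' condition-A (e.g. 1.5-T) cohort mean.
#'
#' @param reference,comparison Numeric means.
#' @return Percent change.
#' @export
percentChange <- function(reference, comparison) {
  if (reference == 0) stop("zero reference level")
  100 * (comparison - reference) / reference
}
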