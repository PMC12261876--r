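## Parameter columns of a per-measurement summary table, with the display
## names used in the report tables.
ventParameters <- function() {
  c(meanRVent = "Mean RVent (mL/mL)",
    covRVent = "CoV RVent (%)",
    vvpRVent = "VVP RVent (%)",
    meanFVLCM = "Mean FVL-CM (-)",
    covFVLCM = "CoV FVL-CM (%)",
    vvpFVLCM = "VVP FVL-CM (%)",
    tidalVolume = "Tidal volume (mL)",
    breathingFrequency = "Breathing frequency (breaths/min)")
}

medianIQR <- function(x)
  sprintf("%.3g (%.3g-%.3g)", median(x),
          quantile(x, 0.25, names = FALSE), quantile(x, 0.75, names = FALSE))

#' Build report tables from per-measurement summaries
#'
#' Assembles the three comparison designs from a cohort summary table (one
#' row per subject x scanner x measurement, parameter columns as in
#' \code{\link{ventParameters}}):
#' \describe{
#'   \item{repeatability}{per scanner and parameter: median (IQR) of both
#'     measurements, Bland-Altman bias, Wilcoxon p, median
#'     between-measurement CoV, ICC(2,1) with Viera-Garrett label, Cohen's d
#'     with Sawilowsky label. Differences are measurement 1 minus
#'     measurement 2.}
#'   \item{intercenter}{subjects age-matched between the two centers at the
#'     common field strength; per measurement and parameter: bias and
#'     Wilcoxon p (center 1 minus center 2).}
#'   \item{field_strength}{per measurement and parameter: bias with percent
#'     change, Wilcoxon p, Cohen's d (1.5 T minus 3 T; percent change is the
#'     3-T mean against the 1.5-T mean).}
#' }
#'
#' @param summaries Data frame of per-measurement summaries with provenance
#'   columns \code{subject_id}, \code{age}, \code{center}, \code{scanner},
#'   \code{field_strength}, \code{measurement}.
#' @param design One of "repeatability", "intercenter", "field_strength".
#' @param holm Apply Holm correction to the Wilcoxon p-values of each table
#'   (off by default; no multiple-testing correction is the primary
#'   analysis).
#' @return A data.frame of table rows; for intercenter designs the
#'   age-matching result is attached as attribute \code{"matching"}.
#' @export
buildTables <- function(summaries,
                        design = c("repeatability", "intercenter",
                                   "field_strength"),
                        holm = FALSE) {
  design <- match.arg(design)
  out <- switch(design,
                repeatability = tableRepeatability(summaries),
                intercenter = tableIntercenter(summaries),
                field_strength = tableFieldStrength(summaries))
  if (holm && nrow(out))
    out$p <- stats::p.adjust(out$p, method = "holm")
  out
}

pairedBySubject <- function(s1, s2, key = "subject_id") {
  common <- intersect(s1[[key]], s2[[key]])
  list(a = s1[match(common, s1[[key]]), , drop = FALSE],
       b = s2[match(common, s2[[key]]), , drop = FALSE],
       dropped = setdiff(union(s1[[key]], s2[[key]]), common))
}

tableRepeatability <- function(summaries) {
  rows <- list()
  for (sc in unique(summaries$scanner)) {
    s <- summaries[summaries$scanner == sc, ]
    pr <- pairedBySubject(s[s$measurement == 1, ], s[s$measurement == 2, ])
    if (length(pr$dropped))
      message("repeatability/", sc, ": dropped unpaired subjects: ",
              paste(pr$dropped, collapse = ", "))
    if (!nrow(pr$a)) next
    for (p in names(ventParameters())) {
      x1 <- pr$a[[p]]; x2 <- pr$b[[p]]
      ba <- blandAltman(x1, x2)
      icc <- tryCatch(iccAbsoluteAgreement(x1, x2), error = function(e) NA)
      d <- tryCatch(cohensDPaired(x1, x2), error = function(e) NA)
      rows[[length(rows) + 1L]] <- data.frame(
        scanner = sc, parameter = ventParameters()[[p]],
        median_iqr_m1 = medianIQR(x1), median_iqr_m2 = medianIQR(x2),
        bias = ba$bias, loa_low = ba$loaLow, loa_high = ba$loaHigh,
        p = wilcoxonSignedRank(x1, x2)$p,
        median_cov = pairwiseCoV(x1, x2)$median,
        icc = as.numeric(icc),
        icc_label = interpretICC(as.numeric(icc)),
        cohens_d = as.numeric(d),
        d_label = interpretEffectSize(as.numeric(d)),
        n = ba$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

tableIntercenter <- function(summaries) {
  fsCommon <- intersect(
    summaries$field_strength[summaries$center == unique(summaries$center)[1]],
    summaries$field_strength[summaries$center == unique(summaries$center)[2]])
  if (!length(fsCommon)) stop("config error: no common field strength")
  fs <- max(fsCommon)
  s <- summaries[summaries$field_strength == fs, ]
  centers <- sort(unique(s$center))
  if (length(centers) != 2L) stop("intercenter design needs two centers")
  subA <- unique(s[s$center == centers[1], c("subject_id", "age")])
  subB <- unique(s[s$center == centers[2], c("subject_id", "age")])
  mt <- ageMatch(subA$age, subB$age, subA$subject_id, subB$subject_id)
  rows <- list()
  for (m in sort(unique(s$measurement))) {
    sm <- s[s$measurement == m, ]
    a <- sm[match(mt$pairs$idA, sm$subject_id), ]
    b <- sm[match(mt$pairs$idB, sm$subject_id), ]
    for (p in names(ventParameters())) {
      ba <- blandAltman(a[[p]], b[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        measurement = m, parameter = ventParameters()[[p]],
        bias = ba$bias, p = wilcoxonSignedRank(a[[p]], b[[p]])$p,
        n = ba$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "matching") <- mt
  out
}

tableFieldStrength <- function(summaries) {
  fs <- sort(unique(summaries$field_strength))
  if (length(fs) != 2L)
    stop("config error: field-strength design needs exactly two ",
         "field strengths")
  lowT <- summaries[summaries$field_strength == fs[1], ]  # 1.5 T reference
  highT <- summaries[summaries$field_strength == fs[2], ]
  rows <- list()
  for (m in sort(unique(summaries$measurement))) {
    pr <- pairedBySubject(lowT[lowT$measurement == m, ],
                          highT[highT$measurement == m, ])
    if (!nrow(pr$a)) next
    for (p in names(ventParameters())) {
      x1 <- pr$a[[p]]; x2 <- pr$b[[p]]   # A = 1.5 T, B = 3 T
      ba <- blandAltman(x1, x2)
      d <- tryCatch(cohensDPaired(x1, x2), error = function(e) NA)
      rows[[length(rows) + 1L]] <- data.frame(
        measurement = m, parameter = ventParameters()[[p]],
        bias = ba$bias,
        pct_change = percentChange(mean(x1), mean(x2)),
        p = wilcoxonSignedRank(x1, x2)$p,
        cohens_d = as.numeric(d),
        d_label = interpretEffectSize(as.numeric(d)),
        n = ba$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
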