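#' Default calibration for the three common posterior fossa tumour types
#'
#' Generator parameters for Medulloblastoma (MB), Ependymoma (EP) and
#' Pilocytic Astrocytoma (PA), calibrated to published multicentre
#' per-tumour ADC histogram statistics: between-patient mean +/- SD of the
#' per-tumour mean ADC (MB 0.870 +/- 0.154, EP 1.126 +/- 0.155,
#' PA 1.656 +/- 0.290, all x10-3 mm^2/s), within-tumour voxel variance
#' (1.00e-7 / 7.89e-8 / 9.49e-8 (mm^2/s)^2), within-tumour skewness
#' (1.40 +/- 0.60 / 1.34 +/- 1.13 / 0.70 +/- 0.83) and the cohort
#' composition 55/26/36. Reference kurtoses are 3.81 / 5.95 / 3.08
#' (Pearson convention).
#'
#' MB is the densely cellular, low-ADC type; PA the microcystic high-ADC
#' type; EP sits between the two and is the hard class. An optional
#' "ATRT" entry shares MB's moments: atypical teratoid rhabdoid tumours
#' overlap MB in ADC and are included only for qualitative demonstration
#' of that overlap, never for training.
#'
#' @param includeATRT also return a 4-case ATRT-like entry with MB-matched
#'   moments (default \code{FALSE}).
#' @param cvWithinVar between-patient coefficient of variation applied to
#'   the within-tumour variance (default 0.5; see the methods vignette for
#'   the rationale).
#' @return Named list of \linkS4class{TumourTypeParams} ("MB", "EP", "PA",
#'   optionally "ATRT").
#' @examples
#' posteriorFossaParams()[["MB"]]
#' @export
posteriorFossaParams <- function(includeATRT = FALSE, cvWithinVar = 0.5) {
    p <- list(
        MB = TumourTypeParams("MB", meanADC = 0.870e-3, sdMeanADC = 0.154e-3,
                              withinVar = 1.00e-7, skew = 1.40, sdSkew = 0.60,
                              kurtosis = 3.81, cvWithinVar = cvWithinVar,
                              nCases = 55L),
        EP = TumourTypeParams("EP", meanADC = 1.126e-3, sdMeanADC = 0.155e-3,
                              withinVar = 7.89e-8, skew = 1.34, sdSkew = 1.13,
                              kurtosis = 5.95, cvWithinVar = cvWithinVar,
                              nCases = 26L),
        PA = TumourTypeParams("PA", meanADC = 1.656e-3, sdMeanADC = 0.290e-3,
                              withinVar = 9.49e-8, skew = 0.70, sdSkew = 0.83,
                              kurtosis = 3.08, cvWithinVar = cvWithinVar,
                              nCases = 36L))
    if (includeATRT)
        p$ATRT <- TumourTypeParams("ATRT", meanADC = 0.870e-3,
                                   sdMeanADC = 0.154e-3, withinVar = 1.00e-7,
                                   skew = 1.40, sdSkew = 0.60,
                                   kurtosis = 3.81,
                                   cvWithinVar = cvWithinVar, nCases = 4L)
    p
}

#' Published reference confusion counts for the three-way classification
#'
#' Per-class correct counts reported for the multicentre cohort (rows =
#' observed class, columns = predicted class), used to verify that the
#' accuracy arithmetic in \code{\link{confusionStats}} reproduces the
#' published percentages. Off-diagonal counts are completed so each row
#' sums to the class size (26 EP, 55 MB, 36 PA).
#'
#' @return List with integer matrices \code{NB} and \code{RF}.
#' @export
referenceConfusionCounts <- function() {
    lab <- c("EP", "MB", "PA")
    nb <- matrix(c(21, 2, 3,
                   9, 46, 0,
                   4, 0, 32), nrow = 3, byrow = TRUE,
                 dimnames = list(observed = lab, predicted = lab))
    rf <- matrix(c(19, 2, 5,
                   3, 52, 0,
                   6, 0, 30), nrow = 3, byrow = TRUE,
                 dimnames = list(observed = lab, predicted = lab))
    list(NB = nb, RF = rf)
}
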