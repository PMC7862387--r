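#' @import methods
NULL

#' Paired diffusion-weighted volumes for one case
#'
#' Container for the two co-registered magnitude volumes a two-point ADC fit
#' needs: the unweighted (b = 0) volume and the diffusion-weighted volume,
#' together with the diffusion weighting \code{b} (s/mm^2) of the latter.
#'
#' @slot s0 3-D numeric array, signal at b = 0.
#' @slot sb 3-D numeric array, signal at b = \code{b}, same dimensions.
#' @slot b single positive numeric, diffusion weighting in s/mm^2.
#' @export
setClass("DWIPair",
    representation(s0 = "array", sb = "array", b = "numeric"))

setValidity("DWIPair", function(object) {
    msg <- character()
    if (!identical(dim(object@s0), dim(object@sb)))
        msg <- c(msg, "s0 and sb must share one shape")
    if (length(object@b) != 1L || !is.finite(object@b) || object@b <= 0)
        msg <- c(msg, "b must be a single positive finite number (s/mm^2)")
    if (length(msg)) msg else TRUE
})

#' Construct a DWIPair
#'
#' @param s0 numeric array, b = 0 volume.
#' @param sb numeric array, diffusion-weighted volume (same shape).
#' @param b diffusion weighting of \code{sb} in s/mm^2 (default 1000).
#' @return A \linkS4class{DWIPair}.
#' @examples
#' p <- DWIPair(array(1000, c(4, 4, 2)),
#'              array(1000 * exp(-1), c(4, 4, 2)), b = 1000)
#' @export
DWIPair <- function(s0, sb, b = 1000) {
    new("DWIPair", s0 = as.array(s0), sb = as.array(sb), b = as.numeric(b))
}

setMethod("show", "DWIPair", function(object) {
    cat("DWIPair: ", paste(dim(object@s0), collapse = " x "),
        " voxels, b = ", object@b, " s/mm^2\n", sep = "")
})

#' @describeIn DWIPair-class b = 0 volume accessor
#' @param object a \code{DWIPair}
#' @export
b0Volume <- function(object) object@s0

#' @describeIn DWIPair-class diffusion-weighted volume accessor
#' @export
bVolume <- function(object) object@sb

#' @describeIn DWIPair-class b-value accessor (s/mm^2)
#' @export
bValue <- function(object) object@b

#' Voxel-wise apparent diffusion coefficient map
#'
#' ADC values in mm^2/s with a validity mask. A voxel is valid when both
#' input signals were strictly positive so the log-ratio was computable;
#' invalid voxels hold \code{NA} and are excluded downstream. Negative ADC
#' (noise pushing the weighted signal above the unweighted one) is retained,
#' not clipped, and counted in \code{nNegative}.
#'
#' @slot adc numeric array, mm^2/s; \code{NA} where invalid.
#' @slot valid logical array of the same shape.
#' @slot nNegative integer, count of valid voxels with adc < 0.
#' @export
setClass("ADCMap",
    representation(adc = "array", valid = "array", nNegative = "integer"))

setValidity("ADCMap", function(object) {
    msg <- character()
    if (!identical(dim(object@adc), dim(object@valid)))
        msg <- c(msg, "adc and valid must share one shape")
    if (any(!is.finite(object@adc[object@valid])))
        msg <- c(msg, "adc must be finite wherever valid")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ADCMap", function(object) {
    cat("ADCMap: ", paste(dim(object@adc), collapse = " x "),
        " voxels, ", sum(object@valid), " valid, ",
        object@nNegative, " negative\n", sep = "")
})

#' @describeIn ADCMap-class ADC volume accessor (mm^2/s)
#' @param object an \code{ADCMap}
#' @export
adcVolume <- function(object) object@adc

#' @describeIn ADCMap-class validity mask accessor
#' @export
validMask <- function(object) object@valid

#' Fixed-grid normalised ADC histogram
#'
#' ROI ADC values binned on a fixed grid (default 180 bins of width
#' 0.022e-3 mm^2/s starting at 0) and normalised to unit area over the
#' in-range values, so histograms from tumours of different sizes are
#' directly comparable. Values falling outside the grid (including negative
#' ADC) are counted in \code{outOfRange}, never silently dropped.
#'
#' @slot breaks numeric vector of bin edges (length nBins + 1).
#' @slot density numeric vector of normalised frequencies (length nBins);
#'   integrates to 1 over the grid.
#' @slot nVoxels integer, number of values offered to the histogram.
#' @slot outOfRange integer, number of values outside the grid.
#' @export
setClass("ADCHistogram",
    representation(breaks = "numeric", density = "numeric",
                   nVoxels = "integer", outOfRange = "integer"))

setValidity("ADCHistogram", function(object) {
    msg <- character()
    if (length(object@breaks) != length(object@density) + 1L)
        msg <- c(msg, "breaks must have one more element than density")
    w <- diff(object@breaks)
    if (any(w <= 0)) msg <- c(msg, "bin edges must be strictly increasing")
    if (object@nVoxels > object@outOfRange) {
        integral <- sum(object@density * w)
        if (abs(integral - 1) > 1e-9)
            msg <- c(msg, sprintf("density must integrate to 1 (got %.12f)",
                                  integral))
    }
    if (any(object@density < 0)) msg <- c(msg, "density must be nonnegative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ADCHistogram", function(object) {
    cat("ADCHistogram: ", length(object@density), " bins of width ",
        format(diff(object@breaks)[1]), " mm^2/s, ",
        object@nVoxels - object@outOfRange, "/", object@nVoxels,
        " values in range\n", sep = "")
})

#' @describeIn ADCHistogram-class bin edges accessor
#' @param object an \code{ADCHistogram} or \code{MeanHistogram}
#' @export
binEdges <- function(object) object@breaks

#' @describeIn ADCHistogram-class normalised frequency accessor
#' @export
binDensity <- function(object) object@density

#' Mean histogram across cases with per-bin spread
#'
#' The per-bin arithmetic mean of a set of normalised case histograms and
#' the per-bin population standard deviation, as drawn with error bars in
#' cohort-average ADC histogram plots.
#'
#' @slot breaks shared bin edges.
#' @slot densityMean per-bin mean of the normalised frequencies.
#' @slot densitySD per-bin population SD of the normalised frequencies.
#' @slot nCases number of histograms averaged.
#' @export
setClass("MeanHistogram",
    representation(breaks = "numeric", densityMean = "numeric",
                   densitySD = "numeric", nCases = "integer"))

setValidity("MeanHistogram", function(object) {
    msg <- character()
    if (length(object@densityMean) != length(object@densitySD))
        msg <- c(msg, "densityMean and densitySD lengths differ")
    if (length(object@breaks) != length(object@densityMean) + 1L)
        msg <- c(msg, "breaks must have one more element than densityMean")
    if (any(object@densitySD < 0)) msg <- c(msg, "densitySD must be >= 0")
    integral <- sum(object@densityMean * diff(object@breaks))
    if (abs(integral - 1) > 1e-9)
        msg <- c(msg, "densityMean must integrate to 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MeanHistogram", function(object) {
    cat("MeanHistogram over ", object@nCases, " cases, ",
        length(object@densityMean), " bins\n", sep = "")
})

#' Calibration parameters for one tumour type
#'
#' Moments of the within- and between-patient ADC distributions that drive
#' the synthetic cohort generator for one tumour type. Patient-level mean
#' ADC is drawn Normal(\code{meanADC}, \code{sdMeanADC}); within each
#' tumour, voxel ADC follows a shifted gamma whose per-case skewness is
#' drawn lognormal with mean \code{skew} and SD \code{sdSkew}, and whose
#' per-case variance is drawn lognormal with mean \code{withinVar} and
#' coefficient of variation \code{cvWithinVar}. \code{kurtosis} is recorded
#' for reference but not matched independently: the gamma family ties it to
#' skewness.
#'
#' @slot label tumour-type name (e.g. "MB", "EP", "PA").
#' @slot meanADC between-patient mean of per-tumour mean ADC, mm^2/s.
#' @slot sdMeanADC between-patient SD of per-tumour mean ADC, mm^2/s.
#' @slot withinVar within-tumour voxel-wise ADC variance, (mm^2/s)^2.
#' @slot skew within-tumour skewness (dimensionless), between-patient mean.
#' @slot sdSkew between-patient SD of the within-tumour skewness.
#' @slot kurtosis within-tumour Pearson kurtosis (Gaussian = 3), reference.
#' @slot cvWithinVar between-patient coefficient of variation of withinVar.
#' @slot nCases default number of cases of this type in a cohort.
#' @export
setClass("TumourTypeParams",
    representation(label = "character", meanADC = "numeric",
                   sdMeanADC = "numeric", withinVar = "numeric",
                   skew = "numeric", sdSkew = "numeric",
                   kurtosis = "numeric", cvWithinVar = "numeric",
                   nCases = "integer"))

setValidity("TumourTypeParams", function(object) {
    msg <- character()
    if (object@sdMeanADC <= 0) msg <- c(msg, "sdMeanADC must be > 0")
    if (object@withinVar <= 0) msg <- c(msg, "withinVar must be > 0")
    if (object@nCases < 1L) msg <- c(msg, "nCases must be >= 1")
    if (object@meanADC <= 0 || object@meanADC >= 3.96e-3)
        msg <- c(msg, "meanADC must lie in (0, 3.96e-3) mm^2/s")
    if (object@sdSkew < 0) msg <- c(msg, "sdSkew must be >= 0")
    if (object@cvWithinVar < 0) msg <- c(msg, "cvWithinVar must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct tumour-type generator parameters
#'
#' @param label tumour-type name.
#' @param meanADC,sdMeanADC between-patient mean and SD of mean ADC, mm^2/s.
#' @param withinVar within-tumour voxel ADC variance, (mm^2/s)^2.
#' @param skew within-tumour skewness (between-patient mean).
#' @param sdSkew between-patient SD of the skewness (0 = fixed shape).
#' @param kurtosis reference Pearson kurtosis (not matched by the gamma
#'   model; recorded for comparison).
#' @param cvWithinVar between-patient CV of the within-tumour variance.
#' @param nCases default case count for this type.
#' @return A \linkS4class{TumourTypeParams}.
#' @export
TumourTypeParams <- function(label, meanADC, sdMeanADC, withinVar, skew,
                             sdSkew = 0, kurtosis = NA_real_,
                             cvWithinVar = 0, nCases = 1L) {
    new("TumourTypeParams", label = label, meanADC = meanADC,
        sdMeanADC = sdMeanADC, withinVar = withinVar, skew = skew,
        sdSkew = sdSkew, kurtosis = as.numeric(kurtosis),
        cvWithinVar = cvWithinVar, nCases = as.integer(nCases))
}

setMethod("show", "TumourTypeParams", function(object) {
    cat("TumourTypeParams '", object@label, "': mean ADC ",
        format(object@meanADC * 1e3), " +/- ",
        format(object@sdMeanADC * 1e3),
        " x10-3 mm^2/s, within-var ", format(object@withinVar),
        ", skew ", object@skew, " +/- ", object@sdSkew,
        ", n = ", object@nCases, "\n", sep = "")
})

#' One synthetic DWI case
#'
#' A simulated patient: diffusion-weighted volume pair, binary tumour ROI
#' and the noiseless ground-truth ADC volume the signals were generated
#' from, enabling exact forward/inverse checks.
#'
#' @slot caseID unique case identifier.
#' @slot label tumour-type name.
#' @slot dwi \linkS4class{DWIPair} of noisy magnitude volumes.
#' @slot roi integer 0/1 array marking tumour voxels.
#' @slot truthADC noiseless ADC volume, mm^2/s.
#' @export
setClass("SyntheticCase",
    representation(caseID = "character", label = "character",
                   dwi = "DWIPair", roi = "array", truthADC = "array"))

setValidity("SyntheticCase", function(object) {
    msg <- character()
    if (!identical(dim(object@roi), dim(object@truthADC)) ||
        !identical(dim(object@roi), dim(object@dwi@s0)))
        msg <- c(msg, "dwi volumes, roi and truthADC must share one shape")
    if (sum(object@roi) < 50) msg <- c(msg, "roi must contain >= 50 voxels")
    if (any(object@truthADC[object@roi == 1] < 0))
        msg <- c(msg, "truthADC must be >= 0 inside the roi")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCase", function(object) {
    cat("SyntheticCase ", object@caseID, " (", object@label, "): roi ",
        sum(object@roi), " voxels\n", sep = "")
})

#' Z-score + principal-component reduction of a feature table
#'
#' Holds per-case component coordinates together with the fitted transform
#' (column means, SDs and loadings) so the identical reduction can be
#' re-applied to external cases.
#'
#' @slot components n x k matrix of case coordinates.
#' @slot nComponents number of components kept.
#' @slot explainedVarianceFraction cumulative variance fraction covered.
#' @slot center,scale per-column z-scoring parameters (kept columns only).
#' @slot rotation column loadings (d x k).
#' @slot keptColumns names of the non-constant columns used.
#' @export
setClass("ReducedFeatures",
    representation(components = "matrix", nComponents = "integer",
                   explainedVarianceFraction = "numeric",
                   center = "numeric", scale = "numeric",
                   rotation = "matrix", keptColumns = "character"))

setValidity("ReducedFeatures", function(object) {
    msg <- character()
    if (ncol(object@components) != object@nComponents)
        msg <- c(msg, "components must have nComponents columns")
    if (object@explainedVarianceFraction < 0 ||
        object@explainedVarianceFraction > 1 + 1e-12)
        msg <- c(msg, "explainedVarianceFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ReducedFeatures", function(object) {
    cat("ReducedFeatures: ", nrow(object@components), " cases x ",
        object@nComponents, " components (",
        sprintf("%.1f%%", 100 * object@explainedVarianceFraction),
        " of variance)\n", sep = "")
})

#' @describeIn ReducedFeatures-class component coordinates accessor
#' @param object a \code{ReducedFeatures}
#' @export
componentScores <- function(object) object@components
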