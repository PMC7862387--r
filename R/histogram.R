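#' Names of the per-case histogram metrics
#'
#' The 22-element feature vector used for classification: min, max, mean,
#' median, variance, skewness, Pearson kurtosis, and the 5th, 10th, 20th,
#' 25th, 35th, 40th, 45th, 50th, 55th, 60th, 70th, 75th, 80th, 85th and
#' 90th quantiles.
#'
#' @return Character vector of metric names in canonical order.
#' @export
metricNames <- function() {
    c("min", "max", "mean", "median", "variance", "skew", "kurtosis",
      paste0("q", c(5, 10, 20, 25, 35, 40, 45, 50, 55, 60, 70, 75, 80,
                    85, 90)))
}

.quantileProbs <- c(5, 10, 20, 25, 35, 40, 45, 50, 55, 60, 70, 75, 80,
                    85, 90) / 100

#' Extract valid ROI ADC values
#'
#' Returns the ADC values at voxels that are inside the ROI and valid in
#' the map, in deterministic raster (column-major linear index) order.
#' Voxels excluded because the fit was invalid are counted in the
#' \code{nInvalid} attribute and logged.
#'
#' @param map an \linkS4class{ADCMap}.
#' @param roi 0/1 array of the same shape.
#' @return Numeric vector of ADC values (mm^2/s) with attribute
#'   \code{nInvalid}.
#' @export
extractROIValues <- function(map, roi) {
    stopifnot(is(map, "ADCMap"))
    if (!identical(dim(roi), dim(map@adc)))
        stop("roi and ADC map shapes differ")
    if (sum(roi == 1) == 0) stop("roi is empty")
    sel <- roi == 1 & map@valid
    if (!any(sel)) stop("roi contains no valid ADC voxels")
    nInvalid <- sum(roi == 1 & !map@valid)
    if (nInvalid > 0)
        message(sprintf("excluded_invalid_voxels=%d", nInvalid))
    structure(map@adc[sel], nInvalid = nInvalid)
}

#' Build a fixed-grid normalised ADC histogram
#'
#' Counts values into half-open bins \eqn{[e_i, e_{i+1})} (the last bin
#' closed above) on a fixed grid — by default 180 bins of width
#' 0.022e-3 mm^2/s starting at 0, spanning [0, 3.96e-3] — and normalises
#' so the in-range density integrates to 1. Values outside the grid
#' (including negative ADC) are counted as out-of-range.
#'
#' @param values numeric vector of ADC values, mm^2/s.
#' @param nBins number of bins (default 180).
#' @param binWidth bin width in mm^2/s (default 0.022e-3).
#' @param origin lower edge of the first bin (default 0).
#' @return An \linkS4class{ADCHistogram}.
#' @examples
#' h <- buildHistogram(rep(0.5e-3, 10))
#' which(binDensity(h) > 0)  # bin 23 (1-based): 0.5/0.022 = 22.7
#' @export
buildHistogram <- function(values, nBins = 180L, binWidth = 0.022e-3,
                           origin = 0) {
    stopifnot(length(values) >= 1, nBins >= 1, binWidth > 0)
    upper <- origin + nBins * binWidth
    idx <- floor((values - origin) / binWidth)
    idx[values == upper] <- nBins - 1L   # close the last bin
    inRange <- idx >= 0 & idx < nBins
    nIn <- sum(inRange)
    if (nIn == 0) stop("all values fall outside the histogram grid")
    counts <- tabulate(idx[inRange] + 1L, nbins = nBins)
    new("ADCHistogram",
        breaks = origin + (0:nBins) * binWidth,
        density = counts / (nIn * binWidth),
        nVoxels = length(values), outOfRange = length(values) - nIn)
}

#' Average histograms across cases
#'
#' Per-bin arithmetic mean of the normalised frequencies and the per-bin
#' population standard deviation (the error bars of cohort-average
#' histogram plots).
#'
#' @param histograms list of \linkS4class{ADCHistogram} on one grid.
#' @return A \linkS4class{MeanHistogram}.
#' @export
meanHistogram <- function(histograms) {
    stopifnot(length(histograms) >= 1)
    breaks <- histograms[[1]]@breaks
    for (h in histograms)
        if (!isTRUE(all.equal(h@breaks, breaks)))
            stop("histograms are not on one grid")
    d <- do.call(rbind, lapply(histograms, function(h) h@density))
    m <- colMeans(d)
    sdPop <- sqrt(colMeans(sweep(d, 2, m)^2))
    new("MeanHistogram", breaks = breaks, densityMean = m,
        densitySD = sdPop, nCases = length(histograms))
}

#' Compute the per-case histogram metric vector
#'
#' Moments and quantiles of the raw ROI ADC values (not of the binned
#' densities, which would quantise them by up to one bin width):
#' skewness \eqn{m_3/m_2^{3/2}} and Pearson kurtosis \eqn{m_4/m_2^2}
#' (Gaussian = 3) from central moments, variance as the second central
#' moment, quantiles by linear interpolation of the empirical
#' distribution. A zero-variance (degenerate) sample reports skew and
#' kurtosis of 0 and carries a \code{degenerate} attribute.
#'
#' @param values numeric vector of at least 2 ADC values, mm^2/s.
#' @param excessKurtosis report kurtosis minus 3 instead (default
#'   \code{FALSE}, i.e. Pearson convention).
#' @return Named numeric vector over \code{\link{metricNames}}, with a
#'   logical \code{degenerate} attribute.
#' @examples
#' computeMetrics(c(1, 2, 3) * 1e-3)[c("mean", "median", "skew")]
#' @export
computeMetrics <- function(values, excessKurtosis = FALSE) {
    stopifnot(length(values) >= 2, all(is.finite(values)))
    m <- mean(values)
    d <- values - m
    m2 <- mean(d^2)
    degenerate <- m2 == 0
    if (degenerate) {
        skew <- 0
        kurt <- 0
    } else {
        skew <- mean(d^3) / m2^1.5
        kurt <- mean(d^4) / m2^2
        if (excessKurtosis) kurt <- kurt - 3
    }
    q <- stats::quantile(values, probs = .quantileProbs, names = FALSE,
                         type = 7)
    out <- c(min(values), max(values), m, stats::median(values), m2, skew,
             kurt, q)
    names(out) <- metricNames()
    attr(out, "degenerate") <- degenerate
    out
}

#' Feature table for a list of in-memory cases
#'
#' Runs ADC computation, ROI extraction and metric computation for each
#' \linkS4class{SyntheticCase} and assembles the classification feature
#' table.
#'
#' @param cases list of \linkS4class{SyntheticCase} (e.g. from
#'   \code{\link{simulateCohort}}).
#' @return \code{data.frame} with columns \code{case_id}, \code{label} and
#'   the 22 \code{\link{metricNames}}.
#' @export
caseFeatureTable <- function(cases) {
    rows <- lapply(cases, function(cs) {
        vals <- extractROIValues(computeADC(cs@dwi), cs@roi)
        cbind(data.frame(case_id = cs@caseID, label = cs@label,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(computeMetrics(vals))))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Feature table for an on-disk cohort
#'
#' Reads each case's volumes named in the manifest, computes the ADC map,
#' extracts valid ROI values and the metric vector, and returns one row
#' per case in manifest order. Re-running on the same inputs gives an
#' identical table.
#'
#' @param manifest manifest \code{data.frame} from
#'   \code{\link{readCohortManifest}} or \code{\link{generateCohort}}.
#' @param b diffusion weighting of the b1000 volumes, s/mm^2.
#' @param outPath optional CSV path the table is also written to.
#' @return \code{data.frame} with \code{case_id}, \code{label} and the 22
#'   metric columns.
#' @export
cohortFeatureTable <- function(manifest, b = 1000, outPath = NULL) {
    dir <- attr(manifest, "dir")
    resolve <- function(p) if (!is.null(dir)) file.path(dir, p) else p
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
        row <- manifest[i, ]
        paths <- resolve(c(row$b0_path, row$b1000_path, row$roi_path))
        if (!all(file.exists(paths)))
            stop("missing volume file(s) for case ", row$case_id)
        pair <- readDWIPair(paths[1], paths[2], b = b)
        roiImg <- RNifti::readNifti(paths[3])
        roi <- array(as.integer(roiImg), dim(roiImg))
        vals <- extractROIValues(computeADC(pair), roi)
        cbind(data.frame(case_id = row$case_id, label = row$label,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(computeMetrics(vals))))
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (!is.null(outPath))
        utils::write.csv(tab, outPath, row.names = FALSE)
    tab
}

#' Extract the numeric metric matrix from a feature table
#'
#' @param table a feature table from \code{\link{cohortFeatureTable}} or
#'   \code{\link{caseFeatureTable}}.
#' @return Numeric matrix (cases x 22) with case_ids as rownames.
#' @export
metricMatrix <- function(table) {
    miss <- setdiff(metricNames(), names(table))
    if (length(miss))
        stop("feature table lacks metric columns: ",
             paste(miss, collapse = ", "))
    m <- as.matrix(table[, metricNames()])
    rownames(m) <- table$case_id
    m
}

#' Write mean histogram to CSV
#'
#' Columns: lower bin edge, per-bin mean density, per-bin SD.
#'
#' @param mh a \linkS4class{MeanHistogram}.
#' @param path output CSV path.
#' @export
writeMeanHistogram <- function(mh, path) {
    utils::write.csv(data.frame(edge = utils::head(mh@breaks, -1),
                                mean = mh@densityMean, sd = mh@densitySD),
                     path, row.names = FALSE)
    invisible(path)
}
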