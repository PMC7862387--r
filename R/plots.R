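#' Plot a cohort-average ADC histogram with per-bin SD error bars
#'
#' @param mh a \linkS4class{MeanHistogram}.
#' @param col line colour.
#' @param add overlay on an existing plot.
#' @param errorEvery draw an error bar every this many bins (default 5,
#'   to keep the plot readable).
#' @param ... further arguments to \code{plot}.
#' @export
plotMeanHistogram <- function(mh, col = "black", add = FALSE,
                              errorEvery = 5, ...) {
    mids <- (utils::head(mh@breaks, -1) + utils::tail(mh@breaks, -1)) / 2
    if (!add)
        graphics::plot(mids * 1e3, mh@densityMean / 1e3, type = "l",
                       col = col,
                       xlab = expression(ADC ~ (10^-3 ~ mm^2 / s)),
                       ylab = "normalised frequency", ...)
    else graphics::lines(mids * 1e3, mh@densityMean / 1e3, col = col)
    i <- seq(1, length(mids), by = errorEvery)
    graphics::arrows(mids[i] * 1e3,
                     (mh@densityMean[i] - mh@densitySD[i]) / 1e3,
                     mids[i] * 1e3,
                     (mh@densityMean[i] + mh@densitySD[i]) / 1e3,
                     angle = 90, code = 3, length = 0.02, col = col)
    invisible(NULL)
}

#' Boxplot of per-case mean ADC by tumour type
#'
#' Median line, quartile box, whiskers at 1.5 IQR, outliers as dots.
#'
#' @param means numeric vector of per-case mean ADC, mm^2/s.
#' @param labels tumour-type label per case.
#' @param ... further arguments to \code{boxplot}.
#' @export
plotMeanADCBoxplot <- function(means, labels, ...) {
    graphics::boxplot(I(means * 1e3) ~ labels, range = 1.5,
                      xlab = "tumour type",
                      ylab = expression(mean ~ ADC ~ (10^-3 ~ mm^2 / s)),
                      ...)
    invisible(NULL)
}

#' Bland-Altman plot for two raters' per-case measurements
#'
#' Scatter of paired differences against paired means with the bias line
#' and 1.96 SD limits of agreement.
#'
#' @param raterA,raterB paired numeric vectors.
#' @param ... further arguments to \code{plot}.
#' @export
plotBlandAltman <- function(raterA, raterB, ...) {
    agr <- interraterAgreement(raterA, raterB)
    avg <- (raterA + raterB) / 2
    d <- raterA - raterB
    graphics::plot(avg, d, xlab = "mean of raters",
                   ylab = "difference between raters", ...)
    graphics::abline(h = agr$bias, lty = 1)
    graphics::abline(h = agr$limitsOfAgreement, lty = 2)
    invisible(agr)
}
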