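#' Compute a voxel-wise ADC map from a b0/b-weighted pair
#'
#' Two-point log-linear fit per voxel:
#' \deqn{ADC = \ln(S_0 / S_b) / b}
#' which equals the least-squares slope of \eqn{\ln S} against \eqn{-b}
#' through the two acquired points. Voxels where either signal is
#' non-positive cannot be fitted and are flagged invalid (\code{NA} in the
#' map) rather than clamped. Negative ADC values — noise pushing
#' \eqn{S_b} above \eqn{S_0} — are retained and counted, not clipped;
#' downstream histogramming counts them as out-of-range.
#'
#' @param pair a \linkS4class{DWIPair}.
#' @return An \linkS4class{ADCMap} (ADC in mm^2/s).
#' @examples
#' p <- DWIPair(array(1000, c(2, 2, 1)), array(1000 * exp(-1), c(2, 2, 1)))
#' adcVolume(computeADC(p))[1]  # 1e-3 mm^2/s
#' @export
computeADC <- function(pair) {
    stopifnot(is(pair, "DWIPair"))
    validObject(pair)
    valid <- pair@s0 > 0 & pair@sb > 0
    if (!any(valid)) stop("no voxel has positive signal in both volumes")
    adc <- array(NA_real_, dim(pair@s0))
    adc[valid] <- log(pair@s0[valid] / pair@sb[valid]) / pair@b
    new("ADCMap", adc = adc, valid = valid,
        nNegative = sum(adc < 0, na.rm = TRUE))
}

#' Quality-control report for a DWI pair
#'
#' Report-only screening of a volume pair before ADC analysis: fraction of
#' voxels with non-positive signal in either volume, fraction where the
#' weighted signal exceeds the unweighted one (which would yield negative
#' ADC), and the positive-signal dynamic range. If a mask is supplied the
#' pair is flagged when the negative-ADC fraction inside the mask exceeds
#' \code{negThreshold}.
#'
#' @param pair a \linkS4class{DWIPair}.
#' @param mask optional 0/1 array (e.g. tumour ROI) over which the
#'   negative-ADC fraction is additionally assessed.
#' @param negThreshold flag threshold for the in-mask negative-ADC
#'   fraction (default 0.05).
#' @return List: \code{fracNonpositive}, \code{fracNegativeADC},
#'   \code{dynamicRange}, and when a mask is given
#'   \code{maskNegativeFrac} plus logical \code{flagged}.
#' @export
qcPair <- function(pair, mask = NULL, negThreshold = 0.05) {
    stopifnot(is(pair, "DWIPair"))
    nonpos <- pair@s0 <= 0 | pair@sb <= 0
    neg <- pair@sb > pair@s0
    pos <- c(pair@s0[pair@s0 > 0], pair@sb[pair@sb > 0])
    out <- list(fracNonpositive = mean(nonpos),
                fracNegativeADC = mean(neg),
                dynamicRange = if (length(pos)) max(pos) / min(pos) else NA,
                flagged = FALSE)
    if (!is.null(mask)) {
        stopifnot(identical(dim(mask), dim(pair@s0)))
        inMask <- mask == 1
        out$maskNegativeFrac <- mean(neg[inMask])
        out$flagged <- out$maskNegativeFrac > negThreshold
    } else {
        out$flagged <- mean(neg) > negThreshold
    }
    out
}

#' Read a DWI pair from NIfTI files
#'
#' @param b0Path,bPath paths to the b = 0 and diffusion-weighted NIfTI
#'   volumes.
#' @param b diffusion weighting of \code{bPath}, s/mm^2.
#' @return A \linkS4class{DWIPair}.
#' @export
readDWIPair <- function(b0Path, bPath, b = 1000) {
    for (p in c(b0Path, bPath))
        if (!file.exists(p)) stop("missing volume file: ", p)
    s0 <- RNifti::readNifti(b0Path)
    sb <- RNifti::readNifti(bPath)
    DWIPair(array(as.numeric(s0), dim(s0)),
            array(as.numeric(sb), dim(sb)), b = b)
}

#' Write an ADC map to NIfTI
#'
#' Stores the ADC volume (mm^2/s, float32; invalid voxels as NaN) with the
#' unit recorded in the header description.
#'
#' @param map an \linkS4class{ADCMap}.
#' @param path output file path (.nii or .nii.gz).
#' @export
writeADCMap <- function(map, path) {
    img <- RNifti::asNifti(map@adc, datatype = "float")
    img$descrip <- "ADC mm^2/s"
    RNifti::writeNifti(img, path)
    invisible(path)
}
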