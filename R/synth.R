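#' Moment-match a shifted gamma distribution
#'
#' Finds the three-parameter (shifted) gamma distribution with a given
#' mean, standard deviation and skewness. The gamma family is used for the
#' within-tumour voxel ADC distribution because tumour ADC histograms are
#' right-skewed with skewness well above what e.g. a skew-normal can reach
#' (its ceiling is < 1, while observed within-tumour skews reach 1.4).
#'
#' Closed-form relations: shape \eqn{k = (2/skew)^2}, scale
#' \eqn{\theta = sd \cdot skew / 2}, shift \eqn{c = mean - k\theta}; the
#' distribution's analytic mean, SD and skewness then equal the inputs
#' exactly. Kurtosis is not a free parameter: the family implies Pearson
#' kurtosis \eqn{3 + 1.5\,skew^2}.
#'
#' @param mean,sd target mean and standard deviation (same units; here
#'   mm^2/s).
#' @param skew target skewness; must be > 0 for a gamma match. A
#'   non-positive skew falls back to a Gaussian spec (flagged in the
#'   return value).
#' @return List with \code{family} ("gamma" or "gaussian") and either
#'   \code{shape}, \code{scale}, \code{shift} or \code{mean}, \code{sd};
#'   always echoes the matched moments.
#' @examples
#' matchShiftedGamma(0.87e-3, sqrt(1e-7), 1.40)
#' @export
matchShiftedGamma <- function(mean, sd, skew) {
    if (!all(is.finite(c(mean, sd, skew))))
        stop("mean, sd and skew must be finite")
    if (sd <= 0) stop("sd must be > 0")
    if (skew <= 0)
        return(list(family = "gaussian", mean = mean, sd = sd, skew = 0))
    shape <- (2 / skew)^2
    scale <- sd * skew / 2
    list(family = "gamma", shape = shape, scale = scale,
         shift = mean - shape * scale, mean = mean, sd = sd, skew = skew)
}

#' Draw from a matched distribution spec
#'
#' @param n number of draws.
#' @param spec a spec from \code{\link{matchShiftedGamma}}.
#' @return Numeric vector of draws (not truncated).
#' @export
rShiftedGamma <- function(n, spec) {
    if (spec$family == "gaussian")
        return(stats::rnorm(n, spec$mean, spec$sd))
    spec$shift + stats::rgamma(n, shape = spec$shape, scale = spec$scale)
}

# lognormal with prescribed arithmetic mean m and SD s (support > 0)
rlnormMeanSD <- function(n, m, s) {
    if (s <= 0) return(rep(m, n))
    sigma2 <- log(1 + (s / m)^2)
    stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Random ellipsoid ROI mask
#'
#' Draws an axis-aligned ellipsoid of roughly the requested voxel volume at
#' a jittered position inside the volume. The largest semi-axes are
#' assigned to the largest volume dimensions so realistic tumour volumes
#' fit inside thin-slab geometries.
#'
#' @param shape integer vector of volume dimensions.
#' @param nVoxels length-2 range of target ROI voxel counts.
#' @return Integer 0/1 array of dimension \code{shape}.
#' @export
makeEllipsoidROI <- function(shape, nVoxels = c(500, 5000)) {
    target <- stats::runif(1, nVoxels[1], nVoxels[2])
    f <- exp(stats::runif(3, -0.25, 0.25))
    f <- f / prod(f)^(1 / 3)
    rBase <- (3 * target / (4 * pi))^(1 / 3)
    # largest radius along the largest dimension
    radii <- numeric(3)
    radii[order(shape, decreasing = TRUE)] <-
        (rBase * f)[order(f, decreasing = TRUE)]
    if (any(2 * (radii + 1) >= shape))
        stop("impossible geometry: requested ROI does not fit the volume")
    slack <- floor(shape / 2 - radii - 1)
    centre <- shape / 2 +
        vapply(pmin(slack, 2), function(s) stats::runif(1, -s, s), 0)
    ax <- lapply(1:3, function(i) (seq_len(shape[i]) - centre[i]) / radii[i])
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    roi <- array(0L, shape)
    roi[d2 <= 1] <- 1L
    if (sum(roi) < 50)
        stop("impossible geometry: ROI smaller than 50 voxels")
    roi
}

# Rician-corrupted magnitude signal: |S + complex Gaussian noise|
addRicianNoise <- function(signal, sigma) {
    if (sigma <= 0) return(signal)
    n <- length(signal)
    re <- signal + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    array(sqrt(re^2 + im^2), dim(signal))
}

#' Generate one synthetic DWI case
#'
#' Forward model for one simulated patient. A patient-level mean ADC is
#' drawn Normal(meanADC, sdMeanADC); per-case within-tumour skewness and
#' variance are drawn lognormal around their type-level targets (SD
#' \code{sdSkew}, CV \code{cvWithinVar}); ROI voxels are then filled with
#' shifted-gamma ADC values matched to those per-case moments, truncated
#' at 0 (truncation rate reported, warning above 1\%). Signals follow the
#' two-point diffusion model \eqn{S_b = S_0 \exp(-b \cdot ADC)} with a
#' constant baseline \eqn{S_0} and tissue-like background, and Rician
#' noise of the given sigma is applied to both magnitude volumes.
#'
#' @param params a \linkS4class{TumourTypeParams}.
#' @param shape volume dimensions (default \code{c(32, 32, 24)}).
#' @param roiVoxels target ROI size range in voxels.
#' @param sigma Rician noise SD in signal units; 0 gives noiseless
#'   volumes for exact tests. The default 25 with \code{s0 = 1000} gives
#'   a b = 0 SNR of 40.
#' @param b diffusion weighting, s/mm^2.
#' @param s0 constant baseline signal.
#' @param backgroundADC ADC assigned to non-tumour voxels, mm^2/s.
#' @param seed integer seed; the case is a pure function of its arguments.
#' @param mu optional forced patient-level mean ADC (testing hook,
#'   bypasses the Normal draw).
#' @param caseID identifier stored in the case.
#' @return A \linkS4class{SyntheticCase}.
#' @examples
#' p <- posteriorFossaParams()[["MB"]]
#' generateCase(p, sigma = 0, seed = 7)
#' @export
generateCase <- function(params, shape = c(32, 32, 24),
                         roiVoxels = c(500, 5000), sigma = 25, b = 1000,
                         s0 = 1000, backgroundADC = 0.8e-3, seed = 1,
                         mu = NULL, caseID = params@label) {
    stopifnot(sigma >= 0, b > 0, s0 > 0)
    set.seed(as.integer(seed))
    if (is.null(mu)) mu <- stats::rnorm(1, params@meanADC, params@sdMeanADC)
    skew_i <- if (params@sdSkew > 0)
        rlnormMeanSD(1, params@skew, params@sdSkew) else params@skew
    var_i <- if (params@cvWithinVar > 0)
        rlnormMeanSD(1, params@withinVar,
                     params@cvWithinVar * params@withinVar)
        else params@withinVar
    roi <- makeEllipsoidROI(shape, roiVoxels)
    nroi <- sum(roi)
    spec <- matchShiftedGamma(mu, sqrt(var_i), skew_i)
    vals <- rShiftedGamma(nroi, spec)
    nTrunc <- sum(vals < 0)
    if (nTrunc > 0) {
        vals[vals < 0] <- 0
        message(sprintf("truncation_rate=%.4f case=%s", nTrunc / nroi,
                        caseID))
        if (nTrunc / nroi > 0.01)
            warning(sprintf("ADC truncation at 0 affected %.1f%% of voxels",
                            100 * nTrunc / nroi))
    }
    truth <- array(backgroundADC, shape)
    truth[roi == 1L] <- vals
    s0vol <- array(s0, shape)
    sbvol <- s0 * exp(-b * truth)
    if (sigma > 0) {
        s0vol <- addRicianNoise(s0vol, sigma)
        sbvol <- addRicianNoise(sbvol, sigma)
    }
    new("SyntheticCase", caseID = caseID, label = params@label,
        dwi = DWIPair(s0vol, sbvol, b), roi = roi, truthADC = truth)
}

# deterministic per-case child seeds from one master seed
childSeeds <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max, n)
}

#' Simulate an in-memory cohort
#'
#' Generates a full labelled cohort of \linkS4class{SyntheticCase} objects
#' without touching disk. Child seeds are derived deterministically from
#' the master seed, so the cohort is a pure function of (params, counts,
#' seed).
#'
#' @param params named list of \linkS4class{TumourTypeParams} (names are
#'   the labels).
#' @param counts named integer vector of cases per label; defaults to the
#'   \code{nCases} stored in \code{params}.
#' @param seed master seed.
#' @param ... passed to \code{\link{generateCase}} (e.g. \code{sigma},
#'   \code{shape}).
#' @return List of \code{SyntheticCase}, with a \code{labels} attribute.
#' @export
simulateCohort <- function(params, counts = NULL, seed = 1, ...) {
    if (is.null(counts))
        counts <- vapply(params, function(p) p@nCases, 1L)
    stopifnot(all(counts >= 1), all(names(counts) %in% names(params)))
    labels <- rep(names(counts), counts)
    ids <- unlist(lapply(names(counts), function(l)
        sprintf("%s_%03d", l, seq_len(counts[[l]]))))
    seeds <- childSeeds(seed, length(labels))
    cases <- vector("list", length(labels))
    for (i in seq_along(labels))
        cases[[i]] <- generateCase(params[[labels[i]]], seed = seeds[i],
                                   caseID = ids[i], ...)
    names(cases) <- ids
    attr(cases, "labels") <- labels
    cases
}

#' Generate a synthetic cohort on disk
#'
#' Writes each case's b = 0, b = 1000 and ROI volumes as uncompressed
#' NIfTI-1 files plus a cohort manifest CSV
#' (\code{case_id,label,b0_path,b1000_path,roi_path}; paths relative to
#' the manifest). Same seed, params and counts give byte-identical files.
#'
#' @inheritParams simulateCohort
#' @param dir output directory (created if needed).
#' @return The manifest \code{data.frame} (invisibly), with attributes
#'   \code{dir} and \code{seed}. Also written to \code{dir/manifest.csv}.
#' @export
generateCohort <- function(params, counts = NULL, dir, seed = 1, ...) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    cases <- simulateCohort(params, counts, seed = seed, ...)
    rows <- lapply(cases, function(cs) {
        paths <- sprintf("%s_%s.nii", cs@caseID, c("b0", "b1000", "roi"))
        RNifti::writeNifti(cs@dwi@s0, file.path(dir, paths[1]))
        RNifti::writeNifti(cs@dwi@sb, file.path(dir, paths[2]))
        RNifti::writeNifti(cs@roi, file.path(dir, paths[3]))
        data.frame(case_id = cs@caseID, label = cs@label,
                   b0_path = paths[1], b1000_path = paths[2],
                   roi_path = paths[3], stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    attr(manifest, "dir") <- dir
    attr(manifest, "seed") <- as.integer(seed)
    invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path path to a \code{manifest.csv} written by
#'   \code{\link{generateCohort}}.
#' @return The manifest \code{data.frame} with a \code{dir} attribute for
#'   resolving the relative volume paths.
#' @export
readCohortManifest <- function(path) {
    manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("case_id", "label", "b0_path", "b1000_path", "roi_path")
    if (!all(need %in% names(manifest)))
        stop("manifest lacks required columns: ",
             paste(setdiff(need, names(manifest)), collapse = ", "))
    if (anyDuplicated(manifest$case_id))
        stop("manifest case_ids must be unique")
    attr(manifest, "dir") <- dirname(normalizePath(path))
    manifest
}
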