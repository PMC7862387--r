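#' Average sensitivity at a fixed mean-ADC cutoff over simulated groups
#'
#' Draws replicate groups of per-tumour mean ADC values from the
#' calibrated between-patient Normal distribution and averages the
#' fraction exceeding a fixed threshold — the expected sensitivity of a
#' published cutoff applied to new cohorts of the same size.
#'
#' @param nReplicates number of simulated groups (default 1000).
#' @param n group size per replicate (default 26, the ependymoma count).
#' @param mean,sd between-patient Normal parameters of the group's mean
#'   ADC, mm^2/s (defaults: the ependymoma calibration).
#' @param cutoff decision threshold, mm^2/s; a case is called positive
#'   when its mean ADC exceeds it.
#' @param seed RNG seed.
#' @return List: \code{sensitivity} (mean over replicates, \%),
#'   \code{bySeed} (per-replicate, \%), \code{nReplicates}.
#' @export
simulatedSensitivityAtCutoff <- function(nReplicates = 1000, n = 26,
                                         mean = 1.126e-3, sd = 0.155e-3,
                                         cutoff = 0.984e-3, seed = 1) {
    set.seed(as.integer(seed))
    sens <- vapply(seq_len(nReplicates), function(i)
        100 * base::mean(stats::rnorm(n, mean, sd) > cutoff), 0)
    list(sensitivity = base::mean(sens), bySeed = sens,
         nReplicates = nReplicates)
}

#' Pipeline round-trip calibration of per-tumour mean ADC
#'
#' Generates cases of one tumour type, runs each through the full
#' ADC-map and ROI-extraction pipeline, and summarises the between-case
#' distribution of the per-case ROI mean ADC — the primary calibration
#' check of the generator against its targets.
#'
#' @param params a \linkS4class{TumourTypeParams}.
#' @param nCases number of cases (default 200).
#' @param sigma Rician noise SD (default 0 for the exact round-trip).
#' @param seed master seed.
#' @param ... passed to \code{\link{generateCase}}.
#' @return List: \code{meanOfMeans} and \code{sdOfMeans} (mm^2/s),
#'   \code{se} (standard error of the mean), \code{perCase} (per-case
#'   summary data.frame with mean, variance, skew).
#' @export
calibrationStudy <- function(params, nCases = 200, sigma = 0, seed = 1,
                             ...) {
    seeds <- childSeeds(seed, nCases)
    rows <- lapply(seq_len(nCases), function(i) {
        cs <- generateCase(params, sigma = sigma, seed = seeds[i],
                           caseID = sprintf("%s_%03d", params@label, i),
                           ...)
        vals <- extractROIValues(computeADC(cs@dwi), cs@roi)
        m <- computeMetrics(vals)
        data.frame(mean = m[["mean"]], variance = m[["variance"]],
                   skew = m[["skew"]], kurtosis = m[["kurtosis"]],
                   q25 = m[["q25"]], n = length(vals))
    })
    perCase <- do.call(rbind, rows)
    list(meanOfMeans = mean(perCase$mean), sdOfMeans = stats::sd(perCase$mean),
         se = stats::sd(perCase$mean) / sqrt(nCases), perCase = perCase)
}

#' Repeated end-to-end synthetic cohort study
#'
#' For each seed, simulates a full labelled cohort, extracts the
#' per-case metric table, runs PCA + naive Bayes 10-fold
#' cross-validation, the mean-ADC ROC between the two low-ADC groups
#' (negative class \code{negLabel}, positive class \code{posLabel}) and
#' the across-type one-way ANOVA — the in-silico analogue of the full
#' published analysis.
#'
#' @param params named list of \linkS4class{TumourTypeParams}.
#' @param counts named case counts (default: from \code{params}).
#' @param seeds integer vector of cohort seeds.
#' @param sigma Rician noise SD (default 25).
#' @param classifier \code{"nb"} or \code{"rf"}.
#' @param posLabel,negLabel ROC classes (defaults "EP" over "MB").
#' @param k folds (default 10).
#' @param ... passed to \code{\link{generateCase}}.
#' @return List: \code{overallAccuracy} (mean, \%), \code{accuracyBySeed},
#'   \code{rocCutoffMean} (mm^2/s), \code{rocCutoffBySeed},
#'   \code{rocSensMean} (\%), \code{rocSensBySeed}, \code{anovaP}
#'   (per-seed p-values), \code{tables} (per-seed feature tables).
#' @export
simulateStudy <- function(params, counts = NULL, seeds = 1:10, sigma = 25,
                          classifier = "nb", posLabel = "EP",
                          negLabel = "MB", k = 10, ...) {
    acc <- cutoffs <- sens <- pvals <- numeric(length(seeds))
    tables <- vector("list", length(seeds))
    for (i in seq_along(seeds)) {
        cases <- simulateCohort(params, counts, seed = seeds[i],
                                sigma = sigma, ...)
        tab <- caseFeatureTable(cases)
        cv <- crossValidate(tab, tab$label, classifier = classifier,
                            k = k, seed = seeds[i])
        acc[i] <- cv$overall
        roc <- rocCutoff(tab$mean[tab$label == posLabel],
                         tab$mean[tab$label == negLabel])
        cutoffs[i] <- roc$optimalCutoff
        sens[i] <- roc$sensAtCutoff
        pvals[i] <- onewayANOVA(split(tab$mean, tab$label))$p
        tables[[i]] <- tab
    }
    list(overallAccuracy = mean(acc), accuracyBySeed = acc,
         rocCutoffMean = mean(cutoffs), rocCutoffBySeed = cutoffs,
         rocSensMean = mean(sens), rocSensBySeed = sens,
         anovaP = pvals, tables = tables)
}

#' ANOVA significance rate over replicate simulated cohorts
#'
#' Draws per-type group samples of per-tumour mean ADC from the
#' calibrated Normal distributions and records the one-way ANOVA p-value
#' per replicate.
#'
#' @param params named list of \linkS4class{TumourTypeParams}.
#' @param counts named group sizes (default: from \code{params}).
#' @param nReplicates number of replicates (default 100).
#' @param seed RNG seed.
#' @return List: \code{p} (vector of p-values), \code{fracBelow} function
#'   of a bound, \code{p99} (99th-percentile p-value).
#' @export
simulatedANOVA <- function(params, counts = NULL, nReplicates = 100,
                           seed = 1) {
    if (is.null(counts))
        counts <- vapply(params, function(p) p@nCases, 1L)
    set.seed(as.integer(seed))
    p <- vapply(seq_len(nReplicates), function(i) {
        groups <- lapply(names(counts), function(l)
            stats::rnorm(counts[[l]], params[[l]]@meanADC,
                         params[[l]]@sdMeanADC))
        onewayANOVA(groups)$p
    }, 0)
    list(p = p,
         fracBelow = function(bound) mean(p < bound),
         p99 = stats::quantile(p, 0.99, names = FALSE, type = 1))
}
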