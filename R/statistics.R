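#' Empirical ROC curve and Youden-optimal cutoff
#'
#' Builds the empirical ROC between two groups of mean ADC values with the
#' higher-ADC group as the positive class and the decision rule
#' "positive when value > threshold". Thresholds are the midpoints between
#' consecutive distinct pooled values, plus sentinels below the minimum
#' and above the maximum; AUC is the trapezoidal area, which equals the
#' Mann-Whitney statistic \eqn{U/(n_1 n_2)} (ties counted half). The
#' optimal cutoff maximises Youden's \eqn{J = sens + spec - 1}; ties are
#' broken towards the lower threshold.
#'
#' @param valuesPos positive-class values (the higher-ADC group, e.g.
#'   ependymoma mean ADCs), mm^2/s.
#' @param valuesNeg negative-class values (e.g. medulloblastoma mean
#'   ADCs).
#' @return List: \code{thresholds}, \code{sensitivity},
#'   \code{specificity} (proportions per threshold), \code{auc},
#'   \code{optimalCutoff}, \code{sensAtCutoff}/\code{specAtCutoff} (\%),
#'   \code{nPosCorrect}/\code{nNegCorrect} (raw counts at the cutoff),
#'   \code{youdenJ}, \code{degenerate}.
#' @export
rocCutoff <- function(valuesPos, valuesNeg) {
    stopifnot(length(valuesPos) >= 1, length(valuesNeg) >= 1)
    pooled <- sort(unique(c(valuesPos, valuesNeg)))
    degenerate <- length(pooled) == 1L
    eps <- if (degenerate) 1 else min(diff(range(pooled)), 1) / 2
    thr <- c(pooled[1] - eps,
             if (length(pooled) > 1)
                 (pooled[-1] + pooled[-length(pooled)]) / 2,
             pooled[length(pooled)] + eps)
    sens <- vapply(thr, function(t) mean(valuesPos > t), 0)
    spec <- vapply(thr, function(t) mean(valuesNeg <= t), 0)
    # trapezoid over (FPR, TPR); FPR decreases as the threshold rises
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
    j <- sens + spec - 1
    best <- which(j == max(j))[1]   # ties: lower threshold
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, optimalCutoff = thr[best],
         sensAtCutoff = 100 * sens[best], specAtCutoff = 100 * spec[best],
         nPosCorrect = sum(valuesPos > thr[best]),
         nNegCorrect = sum(valuesNeg <= thr[best]),
         youdenJ = j[best], degenerate = degenerate)
}

#' One-way ANOVA across tumour-type groups
#'
#' Classic fixed-effects one-way ANOVA (\eqn{F = MS_{between} /
#' MS_{within}}) on per-tumour mean ADC values, via
#' \code{stats::oneway.test} with equal variances assumed.
#'
#' @param groups list of numeric vectors, one per group (each of length
#'   at least 2).
#' @return List: \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
onewayANOVA <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2)
    if (any(vapply(groups, length, 1L) < 2))
        stop("each group needs at least 2 values")
    values <- unlist(groups)
    if (stats::var(values) == 0)
        stop("degenerate input: all values identical")
    g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
    fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
    list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
         df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}

#' Inter-rater agreement for paired per-case measurements
#'
#' Pearson correlation plus Bland-Altman statistics for two raters'
#' per-case mean ADC values: bias (mean of rater A minus rater B), limits
#' of agreement (bias +/- 1.96 SD of the paired differences) and the
#' repeatability coefficient CR = 1.96 SD of the paired differences.
#'
#' @param raterA,raterB paired numeric vectors (length >= 3).
#' @return List: \code{pearsonR}, \code{bias},
#'   \code{repeatabilityCoefficient}, \code{limitsOfAgreement} (length
#'   2), \code{n}, \code{degenerate} (TRUE when either rater has zero
#'   variance, in which case \code{pearsonR} is \code{NA}).
#' @export
interraterAgreement <- function(raterA, raterB) {
    stopifnot(length(raterA) == length(raterB), length(raterA) >= 3)
    degenerate <- stats::var(raterA) == 0 || stats::var(raterB) == 0
    r <- if (degenerate) NA_real_ else stats::cor(raterA, raterB)
    d <- raterA - raterB
    bias <- mean(d)
    sdd <- stats::sd(d)
    list(pearsonR = r, bias = bias,
         repeatabilityCoefficient = 1.96 * sdd,
         limitsOfAgreement = bias + c(-1.96, 1.96) * sdd,
         n = length(d), degenerate = degenerate)
}

#' Per-metric paired rater comparison with Bonferroni correction
#'
#' Two-tailed paired t-test per metric column between two raters' feature
#' tables; a metric is flagged significant when its p-value falls below
#' 0.05 divided by the number of metrics tested.
#'
#' @param metricsA,metricsB data.frames with identical metric columns
#'   (non-numeric columns such as \code{case_id}/\code{label} are
#'   ignored), rows paired by position.
#' @param alpha family-wise error rate (default 0.05).
#' @return \code{data.frame}: \code{metric}, \code{t}, \code{p},
#'   \code{significant}, with the adjusted \code{threshold} as an
#'   attribute.
#' @export
metricRaterTests <- function(metricsA, metricsB, alpha = 0.05) {
    numA <- names(metricsA)[vapply(metricsA, is.numeric, TRUE)]
    numB <- names(metricsB)[vapply(metricsB, is.numeric, TRUE)]
    if (!identical(sort(numA), sort(numB)))
        stop("metric columns differ between the two tables")
    stopifnot(nrow(metricsA) == nrow(metricsB))
    cols <- numA
    m <- length(cols)
    threshold <- alpha / m
    res <- lapply(cols, function(cl) {
        d <- metricsA[[cl]] - metricsB[[cl]]
        n <- length(d)
        if (stats::sd(d) == 0) {
            t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
            p <- if (mean(d) == 0) 1 else 0
        } else {
            tt <- stats::t.test(metricsA[[cl]], metricsB[[cl]],
                                paired = TRUE)
            t <- unname(tt$statistic)
            p <- tt$p.value
        }
        data.frame(metric = cl, t = t, p = p,
                   significant = p < threshold,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    attr(out, "threshold") <- threshold
    out
}
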