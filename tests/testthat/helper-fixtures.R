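# small, fast fixtures shared across the suite

tinyGeom <- list(shape = c(16, 16, 12), roiVoxels = c(60, 150))

tinyParams <- function(label = "T", meanADC = 1.0e-3, sdMeanADC = 0.1e-3,
                       withinVar = 1e-8, skew = 1, ...) {
    TumourTypeParams(label, meanADC = meanADC, sdMeanADC = sdMeanADC,
                     withinVar = withinVar, skew = skew, ...)
}

genTinyCase <- function(params, ...) {
    do.call(generateCase, c(list(params), tinyGeom, list(...)))
}

# three widely separated, nearly point-mass tumour types: with these the
# classes collapse to distinct constants and any sane classifier is exact
separatedParams <- function(nCases = 4L) {
    # withinVar far below double-precision resolution at these means, so
    # noiseless ROI values are numerically constant per case
    list(A = tinyParams("A", 0.5e-3, 1e-9, 1e-44, 1, nCases = nCases),
         B = tinyParams("B", 1.5e-3, 1e-9, 1e-44, 1, nCases = nCases),
         C = tinyParams("C", 2.5e-3, 1e-9, 1e-44, 1, nCases = nCases))
}

# 6-neighbour binary dilation / erosion for perturbed-rater masks
shiftArr <- function(a, d, k) {
    out <- array(0L, dim(a))
    n <- dim(a)[d]
    if (abs(k) >= n) return(out)
    src <- dst <- lapply(dim(a), seq_len)
    src[[d]] <- if (k > 0) 1:(n - k) else (1 - k):n
    dst[[d]] <- if (k > 0) (1 + k):n else 1:(n + k)
    do.call(`[<-`, c(list(out), dst,
                     list(do.call(`[`, c(list(a), src)))))
}

dilateMask <- function(m) {
    out <- m
    for (d in 1:3) for (k in c(-1L, 1L))
        out <- pmax(out, shiftArr(m, d, k))
    array(as.integer(out > 0), dim(m))
}

erodeMask <- function(m) {
    out <- m
    for (d in 1:3) for (k in c(-1L, 1L))
        out <- pmin(out, shiftArr(m, d, k))
    array(as.integer(out > 0), dim(m))
}

# direct definitional Pearson correlation, independent of stats::cor
pearsonOracle <- function(a, b) {
    da <- a - mean(a); db <- b - mean(b)
    sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# pair-counting Mann-Whitney AUC oracle (ties count half)
aucOracle <- function(pos, neg) {
    s <- 0
    for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
    s / (length(pos) * length(neg))
}
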