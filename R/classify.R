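#' Z-score and PCA-reduce a metric table
#'
#' Columns are standardised to zero mean and unit variance (constant
#' columns are dropped with a warning — they carry no information and
#' cannot be z-scored), then projected onto the leading principal
#' components. The smallest number of components whose cumulative
#' explained variance reaches \code{varianceTarget} is kept, capped at
#' \code{maxComponents}; when the cap binds, the explained fraction may
#' fall short of the target.
#'
#' @param x numeric matrix or data.frame of per-case metrics (cases in
#'   rows).
#' @param varianceTarget cumulative explained-variance goal (default
#'   0.95).
#' @param maxComponents component cap (default 10).
#' @return A \linkS4class{ReducedFeatures} carrying the scores and the
#'   full transform for reuse on external data.
#' @export
pcaReduce <- function(x, varianceTarget = 0.95, maxComponents = 10L) {
    x <- as.matrix(x)
    stopifnot(nrow(x) >= 2, !anyNA(x))
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
        warning("dropping constant column(s): ",
                paste(colnames(x)[sds == 0], collapse = ", "))
        x <- x[, sds > 0, drop = FALSE]
        sds <- sds[sds > 0]
    }
    if (ncol(x) == 0) stop("no non-constant columns remain")
    ctr <- colMeans(x)
    z <- scale(x, center = ctr, scale = sds)
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    evf <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- min(which(evf >= varianceTarget - 1e-12), maxComponents,
             length(evf))
    new("ReducedFeatures",
        components = pc$x[, seq_len(k), drop = FALSE],
        nComponents = as.integer(k),
        explainedVarianceFraction = evf[k],
        center = ctr, scale = sds,
        rotation = pc$rotation[, seq_len(k), drop = FALSE],
        keptColumns = colnames(x))
}

#' Apply a fitted reduction to new cases
#'
#' @param reduced a \linkS4class{ReducedFeatures} from
#'   \code{\link{pcaReduce}}.
#' @param x new metric matrix/data.frame with (at least) the kept
#'   columns.
#' @return Matrix of component scores for the new cases.
#' @export
applyReduction <- function(reduced, x) {
    x <- as.matrix(as.data.frame(x))
    miss <- setdiff(reduced@keptColumns, colnames(x))
    if (length(miss))
        stop("new data lacks column(s): ", paste(miss, collapse = ", "))
    z <- scale(x[, reduced@keptColumns, drop = FALSE],
               center = reduced@center, scale = reduced@scale)
    z %*% reduced@rotation
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Per class and per feature a univariate Gaussian is fitted; class priors
#' are the training frequencies. Within-class variances are floored at
#' 1e-9 times the pooled within-class variance of the feature so a
#' degenerate class cannot produce infinite densities.
#'
#' @param x numeric matrix of training features (e.g. component scores).
#' @param y class labels (coerced to character).
#' @return An object of class \code{pfNaiveBayes}.
#' @export
nbFit <- function(x, y) {
    x <- as.matrix(x)
    y <- as.character(y)
    stopifnot(nrow(x) == length(y))
    classes <- sort(unique(y))
    means <- t(matrix(vapply(classes, function(cl)
        colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))),
        nrow = ncol(x)))
    vars <- t(matrix(vapply(classes, function(cl) {
        v <- apply(x[y == cl, , drop = FALSE], 2, stats::var)
        ifelse(is.na(v), 0, v)
    }, numeric(ncol(x))), nrow = ncol(x)))
    n <- vapply(classes, function(cl) sum(y == cl), 1L)
    # pooled within-class variance per feature, for the variance floor
    pooled <- colSums(vars * pmax(n - 1L, 0L)) / max(sum(n) - length(n), 1L)
    floorv <- pmax(1e-9 * pooled, .Machine$double.xmin)
    vars <- pmax(vars, matrix(floorv, nrow(vars), ncol(vars), byrow = TRUE))
    structure(list(classes = classes, means = means, vars = vars,
                   priors = n / sum(n)),
              class = "pfNaiveBayes")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Posteriors are proportional to prior times the product of univariate
#' Gaussian densities (computed in log space); ties in the argmax are
#' broken towards the lexicographically first class name.
#'
#' @param model a \code{pfNaiveBayes} from \code{\link{nbFit}}.
#' @param x feature matrix of cases to classify.
#' @return List with \code{labels} (character) and \code{posterior}
#'   (cases x classes matrix, rows summing to 1).
#' @export
nbPredict <- function(model, x) {
    x <- as.matrix(x)
    if (nrow(x) == 0)
        return(list(labels = character(0),
                    posterior = matrix(0, 0, length(model$classes),
                                       dimnames = list(NULL,
                                                       model$classes))))
    logpost <- vapply(seq_along(model$classes), function(k) {
        mu <- model$means[k, ]
        v <- model$vars[k, ]
        log(model$priors[k]) + apply(x, 1, function(row)
            sum(stats::dnorm(row, mu, sqrt(v), log = TRUE)))
    }, numeric(nrow(x)))
    logpost <- matrix(logpost, nrow = nrow(x),
                      dimnames = list(rownames(x), model$classes))
    post <- exp(logpost - apply(logpost, 1, max))
    post <- post / rowSums(post)
    # which.max returns the first maximum; classes are sorted, so ties
    # resolve to the lexicographically lowest class name
    list(labels = model$classes[apply(logpost, 1, which.max)],
         posterior = post)
}

#' Fit a random forest classifier
#'
#' Standard random forest (bootstrap per tree, CART splits by Gini
#' impurity, floor(sqrt(d)) candidate features per split, majority vote)
#' via the randomForest package, seeded for determinism. Defaults to 100
#' trees.
#'
#' @param x training feature matrix.
#' @param y class labels.
#' @param nTree number of trees (default 100).
#' @param seed RNG seed fixed before fitting (default 0).
#' @param ... passed to \code{\link[randomForest]{randomForest}} (e.g.
#'   \code{maxnodes}).
#' @return A \code{randomForest} fit.
#' @export
rfFit <- function(x, y, nTree = 100, seed = 0, ...) {
    if (nTree < 1) stop("nTree must be >= 1")
    x <- as.data.frame(as.matrix(x))
    y <- factor(as.character(y), levels = sort(unique(as.character(y))))
    set.seed(as.integer(seed))
    randomForest::randomForest(x, y, ntree = nTree, ...)
}

#' Predict with a random forest model
#'
#' @param model fit from \code{\link{rfFit}}.
#' @param x feature matrix of cases to classify.
#' @return List with \code{labels} and \code{votes} (vote fractions).
#' @export
rfPredict <- function(model, x) {
    x <- as.data.frame(as.matrix(x))
    if (nrow(x) == 0)
        return(list(labels = character(0), votes = NULL))
    colnames(x) <- rownames(model$importance)
    list(labels = as.character(stats::predict(model, x)),
         votes = stats::predict(model, x, type = "vote"))
}

#' Accuracy summaries of a confusion matrix
#'
#' @param counts K x K matrix of observed (rows) vs predicted (columns)
#'   counts.
#' @return List: \code{perClass} (per-class recall, \%), \code{overall}
#'   (trace/total, \%), \code{balanced} (mean per-class recall, \%),
#'   \code{n}.
#' @examples
#' confusionStats(referenceConfusionCounts()$NB)
#' @export
confusionStats <- function(counts) {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
    perClass <- 100 * diag(counts) / rowSums(counts)
    list(perClass = perClass,
         overall = 100 * sum(diag(counts)) / sum(counts),
         balanced = mean(perClass),
         n = sum(counts))
}

# deterministic stratified fold assignment
stratifiedFolds <- function(labels, k, seed) {
    folds <- integer(length(labels))
    set.seed(as.integer(seed))
    for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

#' Cross-validated classification of a feature table
#'
#' The paper-style evaluation: the metric table is z-scored and
#' PCA-reduced on the full data (the published processing order;
#' \code{pcaInFold = TRUE} instead refits the reduction inside each
#' training fold, avoiding that leakage), folds are stratified by class,
#' and out-of-fold predictions are pooled into a single confusion matrix
#' from which per-class, overall and balanced accuracies are computed.
#'
#' @param features metric matrix or feature table (cases x metrics).
#' @param labels class label per case.
#' @param classifier \code{"nb"} (Gaussian naive Bayes) or \code{"rf"}
#'   (random forest).
#' @param k number of folds (default 10).
#' @param seed seed controlling fold assignment and the forest.
#' @param nTree random forest size (default 100).
#' @param varianceTarget,maxComponents PCA settings (defaults 0.95, 10).
#' @param pcaInFold refit the reduction within each training fold.
#' @return List: \code{confusion} (K x K matrix), \code{perClass},
#'   \code{overall}, \code{balanced} (accuracies, \%), \code{folds},
#'   \code{predictions}, \code{classifier}, \code{seed}.
#' @export
crossValidate <- function(features, labels, classifier = c("nb", "rf"),
                          k = 10, seed = 0, nTree = 100,
                          varianceTarget = 0.95, maxComponents = 10L,
                          pcaInFold = FALSE) {
    classifier <- match.arg(classifier)
    if (is.data.frame(features) && all(metricNames() %in% names(features)))
        features <- metricMatrix(features)
    features <- as.matrix(features)
    labels <- as.character(labels)
    stopifnot(nrow(features) == length(labels))
    n <- nrow(features)
    if (k > n) stop("k exceeds the number of cases")
    minClass <- min(table(labels))
    if (minClass < k)
        warning("smallest class has fewer members (", minClass,
                ") than folds (", k, "); stratification is relaxed")
    if (!pcaInFold) {
        red <- pcaReduce(features, varianceTarget, maxComponents)
        scores <- componentScores(red)
    }
    folds <- stratifiedFolds(labels, k, seed)
    pred <- character(n)
    for (f in seq_len(k)) {
        test <- folds == f
        if (!any(test)) next
        if (pcaInFold) {
            redf <- pcaReduce(features[!test, , drop = FALSE],
                              varianceTarget, maxComponents)
            trainX <- componentScores(redf)
            testX <- applyReduction(redf, features[test, , drop = FALSE])
        } else {
            trainX <- scores[!test, , drop = FALSE]
            testX <- scores[test, , drop = FALSE]
        }
        pred[test] <- if (classifier == "nb")
            nbPredict(nbFit(trainX, labels[!test]), testX)$labels
        else
            rfPredict(rfFit(trainX, labels[!test], nTree = nTree,
                            seed = seed + f), testX)$labels
    }
    lev <- sort(unique(labels))
    confusion <- table(observed = factor(labels, lev),
                       predicted = factor(pred, lev))
    confusion <- matrix(confusion, nrow = length(lev),
                        dimnames = list(observed = lev, predicted = lev))
    stats <- confusionStats(confusion)
    list(confusion = confusion, perClass = stats$perClass,
         overall = stats$overall, balanced = stats$balanced,
         folds = folds, predictions = pred, classifier = classifier,
         seed = seed)
}

#' Cross-validation averaged over seed replicates
#'
#' Repeats \code{\link{crossValidate}} over several fold seeds and
#' averages the accuracies, taming fold-assignment noise.
#'
#' @inheritParams crossValidate
#' @param seeds integer vector of fold seeds.
#' @return List: \code{overall}, \code{balanced} (mean, \%),
#'   \code{overallBySeed}, \code{results} (per-seed CV results).
#' @export
crossValidateReplicates <- function(features, labels, classifier = "nb",
                                    seeds = 0:9, ...) {
    results <- lapply(seeds, function(s)
        crossValidate(features, labels, classifier = classifier,
                      seed = s, ...))
    ov <- vapply(results, `[[`, 0, "overall")
    list(overall = mean(ov),
         balanced = mean(vapply(results, `[[`, 0, "balanced")),
         overallBySeed = ov, results = results)
}

#' Fit a full-data classifier bundle for external application
#'
#' Fits the reduction and the classifier on all supplied cases and
#' packages both so new cases (e.g. a rare tumour type never seen in
#' training) can be pushed through the identical transform and
#' classified.
#'
#' @inheritParams crossValidate
#' @return List of class \code{pfClassifierBundle}.
#' @export
fitClassifier <- function(features, labels, classifier = c("nb", "rf"),
                          nTree = 100, seed = 0, varianceTarget = 0.95,
                          maxComponents = 10L) {
    classifier <- match.arg(classifier)
    if (is.data.frame(features) && all(metricNames() %in% names(features)))
        features <- metricMatrix(features)
    red <- pcaReduce(features, varianceTarget, maxComponents)
    x <- componentScores(red)
    model <- if (classifier == "nb") nbFit(x, labels)
             else rfFit(x, labels, nTree = nTree, seed = seed)
    structure(list(reduction = red, model = model, classifier = classifier),
              class = "pfClassifierBundle")
}

#' Classify external cases with a fitted bundle
#'
#' @param bundle a \code{pfClassifierBundle} from
#'   \code{\link{fitClassifier}}.
#' @param features metric table or matrix of new cases (columns must
#'   include the training metrics).
#' @return Character vector of predicted labels (empty input gives an
#'   empty output).
#' @export
classifyExternal <- function(bundle, features) {
    stopifnot(inherits(bundle, "pfClassifierBundle"))
    if (is.data.frame(features) && all(metricNames() %in% names(features)))
        features <- metricMatrix(features)
    features <- as.matrix(features)
    if (nrow(features) == 0) return(character(0))
    x <- applyReduction(bundle$reduction, features)
    if (bundle$classifier == "nb") nbPredict(bundle$model, x)$labels
    else rfPredict(bundle$model, x)$labels
}
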