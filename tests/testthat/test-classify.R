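test_that("PCA reduction keeps exactly the needed components", {
    set.seed(1)
    # rank-1 data: all 22 metrics are multiples of one latent factor
    latent <- rnorm(40)
    x <- outer(latent, runif(22, 0.5, 2))
    colnames(x) <- metricNames()
    red <- pcaReduce(x)
    expect_identical(red@nComponents, 1L)
    expect_equal(red@explainedVarianceFraction, 1, tolerance = 1e-9)

    # isotropic data: every direction carries ~1/22 of the variance, so
    # the 10-component cap binds before 95% is reached
    z <- matrix(rnorm(117 * 22), 117, 22, dimnames = list(NULL,
                                                          metricNames()))
    redIso <- pcaReduce(z)
    expect_identical(redIso@nComponents, 10L)
    expect_lt(redIso@explainedVarianceFraction, 0.95)
})

test_that("PCA on z-scores is invariant to column rescaling", {
    set.seed(2)
    x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, letters[1:5]))
    xs <- x
    xs[, 3] <- 7 * xs[, 3] + 0.5   # affine rescaling dies in the z-score
    r1 <- pcaReduce(x, varianceTarget = 0.99)
    r2 <- pcaReduce(xs, varianceTarget = 0.99)
    expect_identical(r1@nComponents, r2@nComponents)
    for (k in seq_len(r1@nComponents))
        expect_equal(abs(componentScores(r1)[, k]),
                     abs(componentScores(r2)[, k]), tolerance = 1e-9)
})

test_that("constant columns are dropped with a warning before z-scoring", {
    set.seed(3)
    x <- cbind(a = rnorm(20), b = rep(4, 20), c = rnorm(20))
    expect_warning(red <- pcaReduce(x), "constant")
    expect_identical(red@keptColumns, c("a", "c"))
    expect_error(suppressWarnings(pcaReduce(cbind(a = rep(1, 5)))),
                 "non-constant")
})

test_that("Gaussian naive Bayes places the symmetric boundary at zero", {
    x <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
    y <- c("a", "a", "a", "b", "b", "b")
    model <- nbFit(x, y)
    pred <- nbPredict(model, matrix(c(-0.01, 0.01, 0), ncol = 1))
    expect_identical(pred$labels[1:2], c("a", "b"))
    # exact tie at the boundary resolves to the lexicographically first
    expect_identical(pred$labels[3], "a")
    expect_equal(pred$posterior[3, ], c(a = 0.5, b = 0.5),
                 tolerance = 1e-12)

    single <- nbFit(matrix(rnorm(5), ncol = 1), rep("only", 5))
    expect_true(all(nbPredict(single,
                              matrix(c(-10, 0, 10), ncol = 1))$labels ==
                    "only"))
})

test_that("naive Bayes posteriors equal the brute-force density product", {
    set.seed(4)
    x <- matrix(rnorm(10 * 3, sd = 2), 10, 3)
    y <- rep(c("u", "v"), each = 5)
    model <- nbFit(x, y)
    pred <- nbPredict(model, x)
    for (i in 1:10) {
        raw <- vapply(c("u", "v"), function(cl) {
            rows <- x[y == cl, , drop = FALSE]
            prior <- mean(y == cl)
            prior * prod(dnorm(x[i, ], colMeans(rows), apply(rows, 2, sd)))
        }, 0)
        expect_equal(pred$posterior[i, ], raw / sum(raw),
                     tolerance = 1e-12)
        expect_identical(pred$labels[i],
                         names(raw)[which.max(raw)])
    }
})

test_that("naive Bayes agrees with an independent implementation", {
    skip_if_not_installed("e1071")
    set.seed(14)
    x <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(c("A", "B", "C"), 60, replace = TRUE)
    ours <- nbPredict(nbFit(x, y), x)
    ref <- e1071::naiveBayes(x, factor(y))
    expect_identical(ours$labels,
                     as.character(predict(ref, x)))
    expect_equal(unname(ours$posterior),
                 unname(predict(ref, x, type = "raw")), tolerance = 1e-6)
})

test_that("random forest is deterministic and separates separable data", {
    x <- matrix(c(seq(-2, -1, length.out = 10),
                  seq(1, 2, length.out = 10)), ncol = 1)
    y <- rep(c("lo", "hi"), each = 10)
    f1 <- rfFit(x, y, nTree = 50, seed = 3)
    expect_identical(rfPredict(f1, x)$labels, y)
    f2 <- rfFit(x, y, nTree = 50, seed = 3)
    set.seed(999)  # prediction must not consume randomness
    expect_identical(rfPredict(f1, x)$labels, rfPredict(f2, x)$labels)
    expect_error(rfFit(x, y, nTree = 0), "nTree")
})

test_that("a depth-one tree cannot solve the XOR layout", {
    x <- matrix(c(0, 0, 1, 1,
                  0, 1, 0, 1), ncol = 2)
    y <- c("a", "b", "b", "a")
    # one tree, one split, trained on all four points: a single
    # axis-aligned split labels at most three points correctly
    f <- rfFit(x, y, nTree = 1, seed = 1, maxnodes = 2,
               replace = FALSE, sampsize = 4)
    acc <- mean(rfPredict(f, x)$labels == y)
    expect_lte(acc, 0.75)
})

test_that("cross-validation is exact on separated classes and conserves counts", {
    set.seed(6)
    n <- 30
    x <- rbind(matrix(rnorm(n * 3, mean = 0, sd = 1e-4), n, 3),
               matrix(rnorm(n * 3, mean = 5, sd = 1e-4), n, 3),
               matrix(rnorm(n * 3, mean = 10, sd = 1e-4), n, 3))
    colnames(x) <- paste0("f", 1:3)
    y <- rep(c("A", "B", "C"), each = n)
    for (cl in c("nb", "rf")) {
        cv <- crossValidate(x, y, classifier = cl, k = 10, seed = 1)
        expect_equal(cv$overall, 100)
        expect_equal(sum(cv$confusion), length(y))
        expect_equal(unname(rowSums(cv$confusion)), rep(n, 3))
    }
})

test_that("accuracy identities hold against brute-force recomputation", {
    set.seed(7)
    x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(c("A", "B", "C"), 60, replace = TRUE)
    cv <- crossValidate(x, y, classifier = "nb", k = 5, seed = 2)
    expect_equal(cv$overall, 100 * mean(cv$predictions == y))
    recalls <- vapply(sort(unique(y)), function(cl)
        100 * mean(cv$predictions[y == cl] == cl), 0)
    expect_equal(cv$perClass, recalls)
    expect_equal(cv$balanced, mean(recalls))
    expect_equal(100 * sum(diag(cv$confusion)) / sum(cv$confusion),
                 cv$overall)
})

test_that("cross-validation is a pure function of its seed", {
    set.seed(8)
    x <- matrix(rnorm(45 * 3), 45, 3, dimnames = list(NULL, paste0("f", 1:3)))
    y <- sample(c("A", "B", "C"), 45, replace = TRUE)
    cv1 <- crossValidate(x, y, classifier = "rf", k = 5, seed = 11)
    cv2 <- crossValidate(x, y, classifier = "rf", k = 5, seed = 11)
    expect_identical(cv1$predictions, cv2$predictions)
    expect_identical(cv1$confusion, cv2$confusion)
    cv3 <- crossValidate(x, y, classifier = "rf", k = 5, seed = 12)
    expect_false(identical(cv1$folds, cv3$folds))
})

test_that("shuffled labels drive accuracy to the chance level", {
    set.seed(9)
    x <- matrix(rnorm(117 * 5), 117, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c("A", "B", "C"), length.out = 117)
    acc <- vapply(1:50, function(s) {
        set.seed(s)
        crossValidate(x, sample(y), classifier = "nb", k = 10,
                      seed = s)$overall
    }, 0)
    expect_lt(abs(mean(acc) - 100 / 3), 3)
})

test_that("stratification warns when a class is smaller than the fold count", {
    set.seed(10)
    x <- matrix(rnorm(24 * 2), 24, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- c(rep("A", 20), rep("B", 4))
    expect_warning(crossValidate(x, y, "nb", k = 10, seed = 1),
                   "stratification")
    expect_error(suppressWarnings(crossValidate(x[1:5, ], y[1:5], "nb",
                                                k = 10, seed = 1)),
                 "exceeds")
})

test_that("external classification reuses the stored transform faithfully", {
    set.seed(11)
    p <- separatedParams(6L)
    cases <- do.call(simulateCohort, c(list(p, seed = 30, sigma = 5),
                                       tinyGeom))
    tab <- caseFeatureTable(cases)
    bundle <- fitClassifier(tab, tab$label, "nb")

    # a training case re-fed gives its resubstitution label
    resub <- classifyExternal(bundle, tab)
    expect_identical(resub, tab$label)

    # empty input gives empty output; mismatched columns error
    expect_identical(classifyExternal(bundle,
                                      metricMatrix(tab)[0, , drop = FALSE]),
                     character(0))
    expect_error(classifyExternal(bundle, metricMatrix(tab)[, 1:5]),
                 "lacks")
})

test_that("ATRT-like cases are absorbed by the medulloblastoma class", {
    # ATRT shares MB's ADC moments; a classifier trained on the three
    # main types should therefore file ATRT-like cases under MB
    p <- posteriorFossaParams(includeATRT = TRUE)
    train <- suppressWarnings(suppressMessages(do.call(simulateCohort,
                     c(list(p[c("MB", "EP", "PA")],
                            counts = c(MB = 20L, EP = 12L, PA = 14L),
                            seed = 40, sigma = 10), tinyGeom))))
    tabTrain <- caseFeatureTable(train)
    bundle <- fitClassifier(tabTrain, tabTrain$label, "nb")
    atrt <- do.call(simulateCohort,
                    c(list(p["ATRT"], counts = c(ATRT = 8L),
                           seed = 41, sigma = 10), tinyGeom))
    pred <- classifyExternal(bundle, caseFeatureTable(atrt))
    expect_identical(names(which.max(table(pred))), "MB")
})
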