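#' Build a pipeline run configuration
#'
#' Defaults reproduce the reference analysis settings end-to-end: a
#' 55/26/36 MB/EP/PA cohort from the calibrated generator, 180 histogram
#' bins of width 0.022e-3 mm^2/s from 0, z-score + PCA to 95\% variance
#' capped at 10 components, Gaussian naive Bayes and 100-tree random
#' forest under stratified 10-fold cross-validation.
#'
#' @param seed master seed for the whole run.
#' @param params named list of \linkS4class{TumourTypeParams}.
#' @param counts named cohort composition (default from \code{params}).
#' @param sigma Rician noise SD (default 25, b = 0 SNR 40).
#' @param shape,roiVoxels generator geometry.
#' @param b diffusion weighting, s/mm^2.
#' @param bins list(n, width, origin) histogram grid.
#' @param folds,nTree,varianceTarget,maxComponents,replicates classifier
#'   settings; \code{replicates} fold-seed replicates to average over.
#' @param outputDir run directory.
#' @param writeADCMaps also write per-case ADC NIfTI volumes.
#' @return List of class \code{pfRunConfig}.
#' @export
runConfig <- function(seed = 1, params = posteriorFossaParams(),
                      counts = NULL, sigma = 25, shape = c(32, 32, 24),
                      roiVoxels = c(500, 5000), b = 1000,
                      bins = list(n = 180L, width = 0.022e-3, origin = 0),
                      folds = 10, nTree = 100, varianceTarget = 0.95,
                      maxComponents = 10L, replicates = 1,
                      outputDir = tempfile("pfadc_run_"),
                      writeADCMaps = FALSE) {
    if (is.null(counts))
        counts <- vapply(params, function(p) p@nCases, 1L)
    structure(list(seed = as.integer(seed), params = params,
                   counts = counts, sigma = sigma, shape = shape,
                   roiVoxels = roiVoxels, b = b, bins = bins,
                   folds = folds, nTree = nTree,
                   varianceTarget = varianceTarget,
                   maxComponents = maxComponents, replicates = replicates,
                   outputDir = outputDir, writeADCMaps = writeADCMaps),
              class = "pfRunConfig")
}

#' Read a run configuration from YAML
#'
#' Any field of \code{\link{runConfig}} may be given; tumour-type
#' parameters are nested maps with keys \code{meanADC}, \code{sdMeanADC},
#' \code{withinVar}, \code{skew}, and optional \code{sdSkew},
#' \code{kurtosis}, \code{cvWithinVar}, \code{nCases}.
#'
#' @param path YAML file path.
#' @return A \code{pfRunConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    if (!is.null(y$params))
        args$params <- lapply(stats::setNames(names(y$params),
                                              names(y$params)),
            function(l) do.call(TumourTypeParams,
                                c(list(label = l), y$params[[l]])))
    for (f in c("seed", "sigma", "b", "folds", "nTree", "varianceTarget",
                "maxComponents", "replicates", "outputDir",
                "writeADCMaps"))
        if (!is.null(y[[f]])) args[[f]] <- y[[f]]
    if (!is.null(y$counts)) args$counts <- unlist(y$counts)
    if (!is.null(y$shape)) args$shape <- unlist(y$shape)
    if (!is.null(y$roiVoxels)) args$roiVoxels <- unlist(y$roiVoxels)
    if (!is.null(y$bins)) args$bins <- y$bins
    do.call(runConfig, args)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON form of the configuration, stamped into
#' every artefact of a run so outputs are traceable to their settings.
#'
#' @param config a \code{pfRunConfig}.
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
    plain <- config
    plain$params <- lapply(plain$params, function(p)
        list(label = p@label, meanADC = p@meanADC,
             sdMeanADC = p@sdMeanADC, withinVar = p@withinVar,
             skew = p@skew, sdSkew = p@sdSkew, kurtosis = p@kurtosis,
             cvWithinVar = p@cvWithinVar, nCases = p@nCases))
    plain$outputDir <- NULL   # location must not change the hash
    plain <- unclass(plain)
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA),
               tmp)
    unname(tools::md5sum(tmp))
}

#' Run the full simulate-to-classify pipeline
#'
#' Executes every stage in order against one run directory: cohort
#' simulation (NIfTI volumes + manifest), ADC maps, per-case feature
#' table (CSV), per-type mean histograms (CSV), NB and RF
#' cross-validation, mean-ADC ANOVA across types and the EP-vs-MB ROC
#' cutoff. Results are written to \code{results.json} stamped with the
#' seed and config hash; warnings and voxel-exclusion messages are
#' captured into \code{run.log}. A stage failure aborts with the stage
#' named.
#'
#' @param config a \code{pfRunConfig} from \code{\link{runConfig}}.
#' @return Invisibly, the results list.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pfRunConfig"))
    dir <- config$outputDir
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create run directory: ", dir)
    logPath <- file.path(dir, "run.log")
    logLines <- character(0)
    note <- function(...) {
        line <- sprintf(...)
        logLines <<- c(logLines, line)
    }
    stage <- function(name, expr) {
        note("stage=%s", name)
        withCallingHandlers(
            tryCatch(expr, error = function(e)
                stop("stage '", name, "' failed: ", conditionMessage(e),
                     call. = FALSE)),
            message = function(m) {
                note("%s", sub("\n$", "", conditionMessage(m)))
                invokeRestart("muffleMessage")
            },
            warning = function(w) {
                note("warning: %s", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
    }
    hash <- configHash(config)
    note("config_hash=%s seed=%d", hash, config$seed)

    manifest <- stage("simulate",
        generateCohort(config$params, config$counts, dir = file.path(dir,
                       "cohort"), seed = config$seed, sigma = config$sigma,
                       shape = config$shape, roiVoxels = config$roiVoxels,
                       b = config$b))
    features <- stage("features",
        cohortFeatureTable(manifest, b = config$b,
                           outPath = file.path(dir, "features.csv")))
    if (isTRUE(config$writeADCMaps))
        stage("adc_maps", {
            adcDir <- file.path(dir, "adc")
            dir.create(adcDir, showWarnings = FALSE)
            for (i in seq_len(nrow(manifest))) {
                p <- file.path(attr(manifest, "dir"),
                               c(manifest$b0_path[i],
                                 manifest$b1000_path[i]))
                writeADCMap(computeADC(readDWIPair(p[1], p[2],
                                                   b = config$b)),
                            file.path(adcDir, paste0(manifest$case_id[i],
                                                     "_adc.nii")))
            }
        })
    stage("mean_histograms", {
        for (l in unique(features$label)) {
            ids <- manifest$case_id[manifest$label == l]
            hs <- lapply(ids, function(id) {
                i <- match(id, manifest$case_id)
                p <- file.path(attr(manifest, "dir"),
                               c(manifest$b0_path[i], manifest$b1000_path[i],
                                 manifest$roi_path[i]))
                roiImg <- RNifti::readNifti(p[3])
                buildHistogram(
                    extractROIValues(computeADC(readDWIPair(p[1], p[2],
                                                            b = config$b)),
                                     array(as.integer(roiImg),
                                           dim(roiImg))),
                    nBins = config$bins$n, binWidth = config$bins$width,
                    origin = config$bins$origin)
            })
            writeMeanHistogram(meanHistogram(hs),
                               file.path(dir, sprintf("mean_histogram_%s.csv",
                                                      l)))
        }
    })
    cv <- stage("classify", {
        seeds <- config$seed + seq_len(config$replicates) - 1
        lapply(stats::setNames(c("nb", "rf"), c("nb", "rf")), function(cl)
            crossValidateReplicates(features, features$label,
                classifier = cl, seeds = seeds, k = config$folds,
                nTree = config$nTree,
                varianceTarget = config$varianceTarget,
                maxComponents = config$maxComponents))
    })
    evalres <- stage("evaluate", {
        groups <- split(features$mean, features$label)
        roc <- if (all(c("EP", "MB") %in% names(groups)))
            rocCutoff(groups$EP, groups$MB) else NULL
        list(anova = onewayANOVA(groups), roc = roc)
    })
    results <- list(
        seed = config$seed, config_hash = hash,
        n_cases = nrow(features),
        classification = lapply(cv, function(r) list(
            overall = r$overall, balanced = r$balanced,
            overall_by_seed = r$overallBySeed,
            confusion = r$results[[1]]$confusion,
            per_class = r$results[[1]]$perClass)),
        anova = evalres$anova,
        roc = if (!is.null(evalres$roc))
            evalres$roc[c("auc", "optimalCutoff", "sensAtCutoff",
                          "specAtCutoff", "nPosCorrect", "nNegCorrect")])
    jsonlite::write_json(results, file.path(dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(logLines, logPath)
    invisible(results)
}

#' Regenerate the headline quantities with pass/fail tolerances
#'
#' Re-runs the scaled experiments behind each headline quantity of the
#' analysis — reference-count accuracy arithmetic, fixed-cutoff
#' sensitivity, generator calibration round-trips, end-to-end NB
#' accuracy, and the ANOVA significance rate — and tabulates each against
#' its reference value and tolerance. Failures are reported in the
#' table, never raised.
#'
#' @param seed master seed.
#' @param nCalibrationCases cases per type for the calibration
#'   round-trips (default 200).
#' @param cohortSeeds seeds for the end-to-end cohort replicates
#'   (default 10).
#' @param nANOVAReplicates replicates for the ANOVA rate (default 100).
#' @param params calibration parameter set.
#' @return \code{data.frame}: \code{quantity}, \code{value},
#'   \code{reference}, \code{tolerance}, \code{pass}.
#' @export
reproduceReport <- function(seed = 1, nCalibrationCases = 200,
                            cohortSeeds = 10, nANOVAReplicates = 100,
                            params = posteriorFossaParams()) {
    rows <- list()
    add <- function(quantity, value, reference, tolerance)
        rows[[length(rows) + 1]] <<- data.frame(
            quantity = quantity, value = value, reference = reference,
            tolerance = tolerance,
            pass = abs(value - reference) <= tolerance,
            stringsAsFactors = FALSE)

    cc <- referenceConfusionCounts()
    nb <- confusionStats(cc$NB)
    rf <- confusionStats(cc$RF)
    add("NB overall accuracy from reference counts (%)", nb$overall,
        84.6, 0.05)
    add("RF overall accuracy from reference counts (%)", rf$overall,
        86.3, 0.05)
    add("NB balanced accuracy from reference counts (%)", nb$balanced,
        84.4, 0.05)
    add("NB EP accuracy from reference counts (%)", nb$perClass[["EP"]],
        80.8, 0.05)

    sens <- simulatedSensitivityAtCutoff(seed = seed)
    add("EP sensitivity at cutoff 0.984e-3 (%)", sens$sensitivity, 80.8, 5)

    for (l in c("MB", "PA")) {
        cal <- calibrationStudy(params[[l]], nCases = nCalibrationCases,
                                sigma = 0, seed = seed)
        add(sprintf("%s mean ADC round-trip (x1e-3 mm^2/s)", l),
            cal$meanOfMeans * 1e3, params[[l]]@meanADC * 1e3,
            3 * cal$se * 1e3)
    }

    study <- simulateStudy(params, seeds = seed + seq_len(cohortSeeds) - 1)
    add("NB 10-fold CV overall accuracy, 117-case cohorts (%)",
        study$overallAccuracy, 85, 5)
    add("EP/MB mean-ADC Youden cutoff (x1e-3 mm^2/s)",
        study$rocCutoffMean * 1e3, 0.984, 0.05)
    add("EP sensitivity at Youden cutoff (%)", study$rocSensMean, 80.8, 5)

    an <- simulatedANOVA(params, nReplicates = nANOVAReplicates,
                         seed = seed)
    add("fraction of ANOVA replicates with p < 0.001",
        an$fracBelow(0.001), 1, 0.01)

    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
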