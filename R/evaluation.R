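#' Leave-one-out cross-validation of the SAE classifier
#'
#' For every subject, a full stacked autoencoder (greedy pretraining,
#' softmax head, fine-tuning) is trained on all remaining subjects' images
#' and the held-out image predicted. Each fold's training seed is derived
#' from the config seed and the fold index, so the whole procedure is
#' deterministic. Predictions are aggregated into one confusion matrix
#' with at_risk as the positive class.
#'
#' @param images n x d matrix of flattened images in [0, 1].
#' @param labels class labels ("at_risk" / "no_risk"), both present, n >= 4.
#' @param n1,n2 encoder layer sizes.
#' @param hyper per-layer hyperparameters (see \code{\link{saeHyper}}).
#' @param config a \linkS4class{TrainConfig}.
#' @return A \linkS4class{ConfusionSummary} over all n predictions.
#' @export
loocvSae <- function(images, labels, n1 = 300L, n2 = 30L,
                     hyper = saeHyper(), config = trainConfig()) {
  X <- as.matrix(images)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present", call. = FALSE)
  preds <- character(n)
  for (i in seq_len(n)) {
    foldCfg <- initialize(config, seed = .deriveSeed(config@seed, 100L, i))
    model <- tryCatch(
      buildAndTrainSae(X[-i, , drop = FALSE], labels[-i], n1, n2, hyper,
                       foldCfg),
      error = function(e)
        stop(sprintf("SAE training failed in fold %d: %s", i,
                     conditionMessage(e)), call. = FALSE))
    preds[i] <- predict(model, X[i, ], type = "class")
  }
  .confusionFromPredictions(preds, labels)
}

#' Full-experiment configuration
#'
#' Bundles the generator, time-frequency, classifier and baseline settings
#' of one end-to-end experiment.
#'
#' @param generator a \linkS4class{GeneratorConfig}.
#' @param fmin,fmax,nBins frequency sweep (defaults 0.05-5 Hz, 100 bins).
#' @param imageHeight,imageWidth rendered image size (default 28 x 28).
#' @param n1,n2 encoder layer sizes.
#' @param hyper SAE hyperparameters.
#' @param train a \linkS4class{TrainConfig}.
#' @param alpha baseline feature-screening significance level.
#' @param nRepeats repeated SAE LOOCV runs with distinct training seeds;
#'   the cohort and its LOOCV partition stay fixed across runs.
#' @param outputDir directory for artifacts, or NA to keep in memory.
#' @return An \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(generator = generatorConfig(),
                             fmin = 0.05, fmax = 5, nBins = 100L,
                             imageHeight = 28L, imageWidth = 28L,
                             n1 = 300L, n2 = 30L,
                             hyper = saeHyper(),
                             train = trainConfig(),
                             alpha = 0.05,
                             nRepeats = 10L,
                             outputDir = NA_character_) {
  new("ExperimentConfig", generator = generator,
      fmin = fmin, fmax = fmax, nBins = as.integer(nBins),
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth),
      n1 = as.integer(n1), n2 = as.integer(n2),
      hyper = hyper, train = train, alpha = alpha,
      nRepeats = as.integer(nRepeats), outputDir = outputDir)
}

.metricsRow <- function(run, axis, method, cs) {
  data.frame(run = run, axis = axis, method = method,
             tp = cs@tp, fp = cs@fp, tn = cs@tn, fn = cs@fn,
             accuracy = accuracy(cs), sensitivity = sensitivity(cs),
             specificity = specificity(cs))
}

#' Run the full two-pipeline experiment
#'
#' Generates the synthetic cohort, converts each axis into time-frequency
#' images, evaluates the stacked-autoencoder classifier per axis under
#' leave-one-out cross-validation (repeated \code{nRepeats} times with
#' distinct training seeds), and in parallel runs the feature-based
#' baseline: 15 statistical features, t-test screening at \code{alpha},
#' and LDA under the same LOOCV scheme. The baseline is deterministic, so
#' its repeated rows are identical; the SAE rows vary only through the
#' training seeds. The report is a pure function of the configuration.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @return An \linkS4class{EvaluationReport}.
#' @export
runExperiment <- function(config) {
  stopifnot(is(config, "ExperimentConfig"))
  validObject(config)
  cohort <- generateCohort(config@generator)
  labels <- riskLabels(cohort)
  grid <- makeFrequencyGrid(config@fmin, config@fmax, config@nBins)

  imagesByAxis <- lapply(stats::setNames(.AXES, .AXES), function(a)
    cohortToImages(cohort, a, grid, config@imageHeight, config@imageWidth))

  ## baseline: features on the full trace, screened once, LDA per axis
  ft <- cohortFeatureTable(cohort)
  featMat <- as.matrix(ft[, .FEATURE_NAMES])
  sel <- selectFeatures(featMat, labels, config@alpha)
  ldaByAxis <- lapply(stats::setNames(.AXES, .AXES), function(a) {
    cols <- grepl(paste0("_", a, "$"), .FEATURE_NAMES) & sel$selected
    if (!any(cols))  # fall back to all per-axis features if none survive
      cols <- grepl(paste0("_", a, "$"), .FEATURE_NAMES)
    loocvLda(featMat[, cols, drop = FALSE], labels)
  })

  metrics <- list()
  seeds <- integer(config@nRepeats)
  for (run in seq_len(config@nRepeats)) {
    runSeed <- .deriveSeed(config@train@seed, 7L, run)
    seeds[run] <- runSeed
    runCfg <- initialize(config@train, seed = runSeed)
    for (a in .AXES) {
      cs <- loocvSae(imagesByAxis[[a]], labels, config@n1, config@n2,
                     config@hyper, runCfg)
      metrics[[length(metrics) + 1L]] <- .metricsRow(run, a, "SAE", cs)
      metrics[[length(metrics) + 1L]] <-
        .metricsRow(run, a, "LDA", ldaByAxis[[a]])
    }
  }
  metrics <- do.call(rbind, metrics)

  report <- new("EvaluationReport", metrics = metrics, config = config,
                provenance = list(masterSeed = config@train@seed,
                                  runSeeds = seeds,
                                  configFingerprint = .fingerprint(config),
                                  timestamp = format(Sys.time(), tz = "UTC")))
  if (!is.na(config@outputDir)) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(config@outputDir, "cohort"))
    utils::write.csv(ft, file.path(config@outputDir, "features.csv"),
                     row.names = FALSE)
    selDf <- data.frame(feature = .FEATURE_NAMES, p_value = sel$pValues,
                        selected = sel$selected)
    utils::write.csv(selDf, file.path(config@outputDir, "selection.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(config@outputDir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(reportToTables(report),
                     file.path(config@outputDir, "summary.csv"),
                     row.names = FALSE)
  }
  report
}

#' @rdname reportToTables
#' @export
reportMetrics <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  report@metrics
}

#' Summarize an evaluation report as a per-axis table
#'
#' Aggregates the stored per-run metrics into one row per axis x method
#' with mean and standard deviation of accuracy, sensitivity and
#' specificity (sd is NA with a single run).
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @return data.frame with 6 rows (3 axes x 2 methods).
#' @export
setMethod("reportToTables", "EvaluationReport", function(report) {
  m <- report@metrics
  out <- list()
  for (a in .AXES) for (meth in c("SAE", "LDA")) {
    sub <- m[m$axis == a & m$method == meth, ]
    if (nrow(sub) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      axis = a, method = meth,
      accuracy_mean = mean(sub$accuracy), accuracy_sd = stats::sd(sub$accuracy),
      sensitivity_mean = mean(sub$sensitivity),
      sensitivity_sd = stats::sd(sub$sensitivity),
      specificity_mean = mean(sub$specificity),
      specificity_sd = stats::sd(sub$specificity))
  }
  if (!length(out))
    return(data.frame(axis = character(), method = character(),
                      accuracy_mean = numeric(), accuracy_sd = numeric(),
                      sensitivity_mean = numeric(), sensitivity_sd = numeric(),
                      specificity_mean = numeric(), specificity_sd = numeric()))
  do.call(rbind, out)
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  master seed %d, %d run(s), fingerprint %s\n",
              object@provenance$masterSeed,
              object@config@nRepeats, object@provenance$configFingerprint))
  print(reportToTables(object), digits = 3)
})
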