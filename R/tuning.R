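#' @include AllClasses.R searchspace.R ber.R coa.R crnn.R extractor.R evaluation.R synthetic.R
NULL

#' Default extractor search space for BER tuning
#'
#' ECA kernel in {3, 5, 7}, width multiplier in `[0.25, 1]`, learning
#' rate in `[1e-4, 1e-1]` (log) and weight decay in `[1e-6, 1e-3]` (log).
#'
#' @return a [SearchSpace-class].
#' @export
extractorSearchSpace <- function() {
  searchSpace(
    hyperParam("ecaKernel", "categorical", choices = c(3, 5, 7)),
    hyperParam("widthMult", "continuous", 0.25, 1.0),
    hyperParam("lr", "continuous", 1e-4, 1e-1, scale = "log"),
    hyperParam("weightDecay", "continuous", 1e-6, 1e-3, scale = "log")
  )
}

#' Default classifier-head search space for COA tuning
#'
#' LSTM units in `[16, 128]`, dropout in `[0, 0.6]`, batch size in
#' {8, 16, 32} and label-smoothing mass in `[0, 0.2]`.
#'
#' @return a [SearchSpace-class].
#' @export
crnnSearchSpace <- function() {
  searchSpace(
    hyperParam("lstmUnits", "integer", 16, 128),
    hyperParam("dropout", "continuous", 0, 0.6),
    hyperParam("batchSize", "categorical", choices = c(8, 16, 32)),
    hyperParam("epsilon", "continuous", 0, 0.2)
  )
}

#' Untuned default hyperparameters
#'
#' The baseline configuration logged next to every tuning run so that
#' tuned-vs-default comparisons are auditable.
#'
#' @return named list with extractor and head defaults.
#' @export
defaultHyperparams <- function() {
  list(
    extractor = list(ecaKernel = 3, widthMult = 1.0, lr = 1e-3,
                     weightDecay = 1e-5),
    head = list(lstmUnits = 32, dropout = 0.2, batchSize = 16,
                epsilon = 0.1)
  )
}

# stage widths from the base topology and a width multiplier, kept
# divisible by the shuffle groups and at least one group wide
scaleWidths <- function(base, mult, groups) {
  as.integer(pmax(groups, roundHalfAway(base * mult / groups) * groups))
}

# the ECA kernel cannot exceed the narrowest stage: clamp to the largest
# odd value that fits (dependent hyperparameter)
clampEcaKernel <- function(k, widths) {
  k <- as.integer(k)
  cmax <- min(widths)
  if (k > cmax) k <- if (cmax %% 2L == 1L) cmax else cmax - 1L
  max(k, 1L)
}

#' Validation error-rate fitness
#'
#' The tuning objective: train briefly with the candidate
#' hyperparameters and return `100 * misclassified / total` on the
#' validation set. A training failure yields `+Inf` with a warning, so
#' the optimizers simply discard the candidate.
#'
#' @param hyperparams named list of decoded hyperparameter values.
#' @param builder function `(hyperparams, trainSet, seed)` returning a
#'   prediction function that maps a [LabeledImageSet-class] to integer
#'   labels.
#' @param trainSet,valSet [LabeledImageSet-class]s; `valSet` must be
#'   non-empty.
#' @param seed integer seed forwarded to the builder.
#' @return percent error in `[0, 100]` (or `+Inf` on failure).
#' @export
fitnessErrorRate <- function(hyperparams, builder, trainSet, valSet,
                             seed = 1) {
  if (!length(valSet)) stop("validation set is empty")
  tryCatch({
    predictFun <- builder(hyperparams, trainSet, seed)
    classifierErrorRate(imageLabels(valSet), predictFun(valSet))
  }, error = function(e) {
    warning(sprintf("trial failed (%s); fitness set to +Inf",
                    conditionMessage(e)), call. = FALSE)
    Inf
  })
}

# shared trial runner: builds the extractor (fixed random features),
# trains the head briefly, returns the validation error and the handles
runTrial <- function(extractorHp, headHp, trainSet, valSet, nClasses,
                     baseWidths, groups, inputSize, epochs, seed,
                     trainFeatures = NULL, valFeatures = NULL,
                     extractor = NULL) {
  if (is.null(extractor)) {
    widths <- scaleWidths(baseWidths, extractorHp$widthMult, groups)
    ecfg <- extractorConfig(
      stageWidths = widths, groups = groups,
      ecaKernel = clampEcaKernel(extractorHp$ecaKernel, widths),
      inputSize = inputSize, seed = deriveSeed(seed, "extractor")
    )
    extractor <- buildExtractor(ecfg)
  }
  if (is.null(trainFeatures)) {
    trainFeatures <- extractorForward(extractor,
                                      imagesToBatch(imageData(trainSet)))
    valFeatures <- extractorForward(extractor,
                                    imagesToBatch(imageData(valSet)))
  }
  ccfg <- crnnConfig(
    convWidths = 16L, dropout = headHp$dropout,
    lstmUnits = as.integer(headHp$lstmUnits), nClasses = nClasses,
    labelSmoothing = headHp$epsilon, seed = deriveSeed(seed, "head")
  )
  crnn <- buildCRNN(ccfg, dim(trainFeatures)[1:3])
  fit <- trainClassifier(extractor, crnn, trainSet, valSet,
                         epochs = epochs,
                         batchSize = as.integer(headHp$batchSize),
                         lr = extractorHp$lr,
                         weightDecay = extractorHp$weightDecay,
                         seed = deriveSeed(seed, "fitness-train"),
                         trainFeatures = trainFeatures,
                         valFeatures = valFeatures)
  err <- fit$history$val_error[epochs]
  list(error = err, extractor = extractor, crnn = fit$model,
       trainFeatures = trainFeatures, valFeatures = valFeatures)
}

#' Tune the extractor hyperparameters with BER
#'
#' Wraps [berOptimize()] over `decodeVector()` of the extractor space
#' composed with the validation error-rate fitness. Every trial is
#' logged (decoded hyperparameters plus fitness).
#'
#' @param trainSet,valSet fitness training and validation sets.
#' @param space a [SearchSpace-class] (default
#'   [extractorSearchSpace()]).
#' @param config a [BERConfig-class]; its seed drives the run.
#' @param headHp head hyperparameters held fixed during extractor
#'   trials (default [defaultHyperparams()]`$head`).
#' @param baseWidths base stage widths scaled by the width multiplier.
#' @param groups shuffle groups.
#' @param trialEpochs per-trial training epochs (a fitness surrogate).
#' @param seed integer seed for the trial training streams.
#' @return list with `best` (`hyperparams`, `fitness`), `trials` data
#'   frame, and the optimizer `history`.
#' @export
runBERTuning <- function(trainSet, valSet, space = extractorSearchSpace(),
                         config = berConfig(populationSize = 5,
                                            iterations = 5),
                         headHp = defaultHyperparams()$head,
                         baseWidths = c(8L, 16L), groups = 2L,
                         trialEpochs = 5, seed = 1) {
  inputSize <- dim(imageData(trainSet)[[1L]])[1]
  nClasses <- length(classNames(trainSet))
  log <- new.env()
  log$rows <- list()
  fitness <- function(x) {
    hp <- decodeVector(x, space)
    res <- tryCatch(
      runTrial(hp, headHp, trainSet, valSet, nClasses, baseWidths,
               groups, inputSize, trialEpochs, seed)$error,
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        Inf
      })
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(trial = length(log$rows) + 1L, as.data.frame(hp),
                 fitness = res)
    res
  }
  run <- berOptimize(fitness, rep(0, length(space)),
                     rep(1, length(space)), config)
  list(
    best = list(hyperparams = decodeVector(run$best$values, space),
                fitness = run$best$fitness),
    trials = do.call(rbind, log$rows),
    history = run$history
  )
}

#' Tune the classifier-head hyperparameters with COA
#'
#' Symmetric to [runBERTuning()], driven by [coaOptimize()]. The
#' extractor hyperparameters (including the training learning rate and
#' weight decay) are fixed to `extractorHp`, so the extractor features
#' are computed once and shared across trials.
#'
#' @param trainSet,valSet fitness training and validation sets.
#' @param extractorHp extractor hyperparameters (e.g. the BER best).
#' @param space a [SearchSpace-class] (default [crnnSearchSpace()]).
#' @param config a [COAConfig-class].
#' @inheritParams runBERTuning
#' @return list with `best`, `trials` and `history` (as in
#'   [runBERTuning()]).
#' @export
runCOATuning <- function(trainSet, valSet,
                         extractorHp = defaultHyperparams()$extractor,
                         space = crnnSearchSpace(),
                         config = coaConfig(populationSize = 5,
                                            iterations = 5),
                         baseWidths = c(8L, 16L), groups = 2L,
                         trialEpochs = 5, seed = 1) {
  inputSize <- dim(imageData(trainSet)[[1L]])[1]
  nClasses <- length(classNames(trainSet))
  widths <- scaleWidths(baseWidths, extractorHp$widthMult, groups)
  ecfg <- extractorConfig(
    stageWidths = widths, groups = groups,
    ecaKernel = clampEcaKernel(extractorHp$ecaKernel, widths),
    inputSize = inputSize, seed = deriveSeed(seed, "extractor")
  )
  extractor <- buildExtractor(ecfg)
  trainFeatures <- extractorForward(extractor,
                                    imagesToBatch(imageData(trainSet)))
  valFeatures <- extractorForward(extractor,
                                  imagesToBatch(imageData(valSet)))
  log <- new.env()
  log$rows <- list()
  fitness <- function(x) {
    hp <- decodeVector(x, space)
    res <- tryCatch(
      runTrial(extractorHp, hp, trainSet, valSet, nClasses, baseWidths,
               groups, inputSize, trialEpochs, seed,
               trainFeatures = trainFeatures, valFeatures = valFeatures,
               extractor = extractor)$error,
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        Inf
      })
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(trial = length(log$rows) + 1L, as.data.frame(hp),
                 fitness = res)
    res
  }
  run <- coaOptimize(fitness, rep(0, length(space)),
                     rep(1, length(space)), config)
  list(
    best = list(hyperparams = decodeVector(run$best$values, space),
                fitness = run$best$fitness),
    trials = do.call(rbind, log$rows),
    history = run$history
  )
}

#' Run the full tuning pipeline
#'
#' Stages, in order: data generation/loading, stratified train/test
#' split, an inner fitness split carved from the training portion, the
#' untuned-default baseline trial, BER tuning of the extractor, COA
#' tuning of the classifier head, final training with the tuned
#' hyperparameters, and evaluation reports for both the training and the
#' held-out split. One global seed determines every stream.
#'
#' @param data a [SyntheticSpec-class] (generated on the fly), a
#'   [LabeledImageSet-class], or a dataset directory path for
#'   [readDataset()].
#' @param splitRatio training fraction (0.8 or 0.7 in the standard
#'   layouts; any value in (0,1) is accepted).
#' @param berCfg,coaCfg optimizer configurations; their seeds are
#'   re-derived from `seed` so one integer reproduces the whole run.
#' @param extractorSpace,headSpace search spaces.
#' @param trialEpochs per-trial training epochs.
#' @param finalEpochs epochs for the final tuned training.
#' @param seed global integer seed.
#' @param outDir optional run directory; when given, trial logs,
#'   optimizer run logs, both reports (CSV + JSON), a checkpoint and a
#'   manifest are written there.
#' @return list with `reports` (`train`, `test`
#'   [EvaluationReport-class]s), `bestExtractor`, `bestHead`,
#'   `tunedError`, `defaultError`, `berRun`, `coaRun`, the final
#'   `model`, and `testAccuracy` (percent).
#' @export
runFullPipeline <- function(data, splitRatio = 0.8,
                            berCfg = berConfig(populationSize = 5,
                                               iterations = 5),
                            coaCfg = coaConfig(populationSize = 5,
                                               iterations = 5),
                            extractorSpace = extractorSearchSpace(),
                            headSpace = crnnSearchSpace(),
                            trialEpochs = 5, finalEpochs = 15,
                            seed = 1, outDir = NULL) {
  if (is(data, "SyntheticSpec")) {
    data <- generateDataset(data)
  } else if (is.character(data)) {
    if (!dir.exists(data)) {
      stop("dataset directory not found; generate one with ",
           "writeDataset() or pass a SyntheticSpec")
    }
    data <- readDataset(data)
  }
  stopifnot(is(data, "LabeledImageSet"))

  sp <- splitDataset(data, splitRatio, seed = seed)
  inner <- splitDataset(sp$train, 0.8, seed = deriveSeed(seed, "val"))
  fitTrain <- inner$train
  fitVal <- inner$test
  nClasses <- length(classNames(data))
  inputSize <- dim(imageData(data)[[1L]])[1]

  defaults <- defaultHyperparams()
  defaultError <- runTrial(defaults$extractor, defaults$head, fitTrain,
                           fitVal, nClasses, c(8L, 16L), 2L, inputSize,
                           trialEpochs, seed)$error

  berCfg@seed <- deriveSeed(seed, "ber")
  ber <- runBERTuning(fitTrain, fitVal, space = extractorSpace,
                      config = berCfg, headHp = defaults$head,
                      trialEpochs = trialEpochs, seed = seed)

  coaCfg@seed <- deriveSeed(seed, "coa")
  coa <- runCOATuning(fitTrain, fitVal,
                      extractorHp = ber$best$hyperparams,
                      space = headSpace, config = coaCfg,
                      trialEpochs = trialEpochs, seed = seed)

  final <- runTrial(ber$best$hyperparams, coa$best$hyperparams,
                    sp$train, sp$test, nClasses, c(8L, 16L), 2L,
                    inputSize, finalEpochs, deriveSeed(seed, "final"))

  trainEval <- evalOnFeatures(final$crnn, final$trainFeatures,
                              imageLabels(sp$train))
  testEval <- evalOnFeatures(final$crnn, final$valFeatures,
                             imageLabels(sp$test))
  splitTag <- sprintf("%d:%d", round(splitRatio * 100),
                      round((1 - splitRatio) * 100))
  reports <- list(
    train = buildReport(imageLabels(sp$train),
                        apply(trainEval$probs, 1L, which.max),
                        trainEval$probs, classNames(data),
                        sprintf("%s train", splitTag)),
    test = buildReport(imageLabels(sp$test),
                       apply(testEval$probs, 1L, which.max),
                       testEval$probs, classNames(data),
                       sprintf("%s test", splitTag))
  )

  result <- list(
    reports = reports,
    bestExtractor = ber$best$hyperparams,
    bestHead = coa$best$hyperparams,
    tunedError = coa$best$fitness,
    defaultError = defaultError,
    berRun = ber, coaRun = coa,
    model = list(extractor = final$extractor, crnn = final$crnn),
    testAccuracy = microAccuracy(
      confusionMatrix(imageLabels(sp$test),
                      apply(testEval$probs, 1L, which.max), nClasses)
    )
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRunLog(ber$history, file.path(outDir, "ber_runlog.csv"))
    writeRunLog(coa$history, file.path(outDir, "coa_runlog.csv"))
    utils::write.csv(ber$trials, file.path(outDir, "ber_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(coa$trials, file.path(outDir, "coa_trials.csv"),
                     row.names = FALSE)
    writeReport(reports$train, file.path(outDir, "report_train.csv"),
                file.path(outDir, "report_train.json"))
    writeReport(reports$test, file.path(outDir, "report_test.csv"),
                file.path(outDir, "report_test.json"))
    saveModel(final$extractor, final$crnn,
              file.path(outDir, "checkpoint.rds"))
    writeLines(c("ber_runlog.csv", "coa_runlog.csv", "ber_trials.csv",
                 "coa_trials.csv", "report_train.csv",
                 "report_train.json", "report_test.csv",
                 "report_test.json", "checkpoint.rds"),
               file.path(outDir, "manifest.txt"))
  }
  result
}
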