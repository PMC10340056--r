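tinySet <- function(n = 6, seed = 1, difficulty = 0.1) {
  generateDataset(syntheticSpec(imagesPerClass = n, imageSize = 16,
                                difficulty = difficulty, seed = seed))
}

test_that("the error-rate fitness is the misclassification percentage", {
  ds <- tinySet(n = 4, seed = 2)
  sp <- splitDataset(ds, 0.6, seed = 2)
  labels <- imageLabels(sp$test)
  constantBuilder <- function(pred) {
    function(hyperparams, trainSet, seed) function(images) pred
  }
  expect_equal(fitnessErrorRate(list(), constantBuilder(labels),
                                sp$train, sp$test), 0)
  allWrong <- (labels %% 5) + 1L
  expect_equal(fitnessErrorRate(list(), constantBuilder(allWrong),
                                sp$train, sp$test), 100)
  eight <- sp$test[1:8]
  y8 <- imageLabels(eight)
  sixOfEight <- y8
  sixOfEight[1:2] <- (y8[1:2] %% 5) + 1L
  expect_equal(fitnessErrorRate(list(), constantBuilder(sixOfEight),
                                sp$train, eight), 25)
  failing <- function(hyperparams, trainSet, seed) stop("boom")
  expect_warning(
    bad <- fitnessErrorRate(list(), failing, sp$train, sp$test),
    "boom"
  )
  expect_equal(bad, Inf)
})

test_that("BER tuning logs every trial and returns the best of them", {
  ds <- tinySet(n = 8, seed = 3)
  sp <- splitDataset(ds, 0.75, seed = 3)
  res <- runBERTuning(sp$train, sp$test,
                      config = berConfig(populationSize = 3,
                                         iterations = 2, seed = 13),
                      trialEpochs = 2, seed = 13)
  expect_true(all(res$trials$fitness >= res$best$fitness))
  expect_equal(min(res$trials$fitness), res$best$fitness)
  expect_true(all(c("ecaKernel", "widthMult", "lr", "weightDecay") %in%
                    names(res$trials)))
  expect_false(is.unsorted(-res$history$best_fitness))
  expect_true(res$best$fitness >= 0 && res$best$fitness <= 100)
  # same seed, same run
  res2 <- runBERTuning(sp$train, sp$test,
                       config = berConfig(populationSize = 3,
                                          iterations = 2, seed = 13),
                       trialEpochs = 2, seed = 13)
  expect_identical(res$best, res2$best)
  expect_identical(res$trials$fitness, res2$trials$fitness)
})

test_that("COA tuning mirrors the BER harness over the head space", {
  ds <- tinySet(n = 8, seed = 4)
  sp <- splitDataset(ds, 0.75, seed = 4)
  res <- runCOATuning(sp$train, sp$test,
                      config = coaConfig(populationSize = 4,
                                         iterations = 2, seed = 14),
                      trialEpochs = 2, seed = 14)
  expect_true(all(res$trials$fitness >= res$best$fitness))
  expect_true(all(c("lstmUnits", "dropout", "batchSize", "epsilon") %in%
                    names(res$trials)))
  expect_false(is.unsorted(-res$history$best_fitness))
  expect_true(res$best$hyperparams$batchSize %in% c(8, 16, 32))
  expect_true(res$best$hyperparams$lstmUnits ==
                round(res$best$hyperparams$lstmUnits))
})

test_that("the full pipeline produces table-shaped reports and artifacts", {
  spec <- syntheticSpec(imagesPerClass = 10, imageSize = 16,
                        difficulty = 0.1, seed = 21)
  outDir <- tempfile("run")
  res <- runFullPipeline(
    spec,
    splitRatio = 0.8,
    berCfg = berConfig(populationSize = 3, iterations = 2),
    coaCfg = coaConfig(populationSize = 4, iterations = 2),
    trialEpochs = 2, finalEpochs = 3, seed = 21, outDir = outDir
  )
  expect_true(res$testAccuracy >= 0 && res$testAccuracy <= 100)
  tab <- reportTable(res$reports$test)
  expect_equal(nrow(tab), 6) # 5 classes + Average
  expect_equal(rownames(tab)[6], "Average")
  expect_equal(colnames(tab),
               c("Accuy", "Precn", "Recal", "Fscore", "AUCscore"))
  expect_true(res$tunedError <= min(res$berRun$trials$fitness))
  expect_true(file.exists(file.path(outDir, "report_test.csv")))
  expect_true(file.exists(file.path(outDir, "ber_trials.csv")))
  expect_true(file.exists(file.path(outDir, "checkpoint.rds")))
  runlog <- read.csv(file.path(outDir, "ber_runlog.csv"))
  expect_equal(colnames(runlog),
               c("iteration", "best_fitness", "mean_fitness",
                 "mutation_fired"))
  unlink(outDir, recursive = TRUE)
})

test_that("pipeline reruns with the same seed reproduce the report", {
  spec <- syntheticSpec(imagesPerClass = 8, imageSize = 16,
                        difficulty = 0.1, seed = 22)
  args <- list(spec, splitRatio = 0.8,
               berCfg = berConfig(populationSize = 3, iterations = 1),
               coaCfg = coaConfig(populationSize = 4, iterations = 1),
               trialEpochs = 1, finalEpochs = 2, seed = 22)
  a <- do.call(runFullPipeline, args)
  b <- do.call(runFullPipeline, args)
  expect_identical(reportTable(a$reports$test),
                   reportTable(b$reports$test))
  expect_identical(a$bestExtractor, b$bestExtractor)
  expect_identical(a$bestHead, b$bestHead)
})
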