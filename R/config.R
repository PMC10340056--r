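#' @include tuning.R
NULL

#' Read and validate a run configuration
#'
#' YAML schema (all optimizer/training constants are surfaced so runs
#' can pin them):
#' \preformatted{
#' seed: 1
#' data:
#'   source: synthetic          # or: directory
#'   directory: path/to/images  # class-per-folder layout
#'   synthetic:
#'     n_classes: 5
#'     images_per_class: 64
#'     image_size: 32
#'     difficulty: 0.2
#' split_ratios: [0.8, 0.7]
#' ber: {population_size: 5, iterations: 5, exploration_fraction: 0.5,
#'       stagnation_window: 3, stagnation_tol: 1.0e-9}
#' coa: {population_size: 5, iterations: 5}
#' training: {trial_epochs: 5, final_epochs: 15}
#' output_dir: runs/demo
#' }
#'
#' @param path YAML file path.
#' @return validated configuration list with all defaults filled in.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  pick <- function(x, nm, default) if (is.null(x[[nm]])) default else x[[nm]]

  out <- list(
    seed = as.integer(pick(cfg, "seed", 1)),
    splitRatios = as.numeric(pick(cfg, "split_ratios", 0.8)),
    outputDir = pick(cfg, "output_dir", NULL)
  )
  if (any(out$splitRatios <= 0 | out$splitRatios >= 1)) {
    stop("split_ratios must lie strictly between 0 and 1")
  }

  dataCfg <- pick(cfg, "data", list())
  source <- pick(dataCfg, "source", "synthetic")
  if (!source %in% c("synthetic", "directory")) {
    stop("data$source must be 'synthetic' or 'directory'")
  }
  if (source == "directory") {
    if (is.null(dataCfg$directory)) {
      stop("data$directory is required when source is 'directory'")
    }
    out$data <- dataCfg$directory
  } else {
    sy <- pick(dataCfg, "synthetic", list())
    out$data <- syntheticSpec(
      nClasses = pick(sy, "n_classes", 5),
      imagesPerClass = pick(sy, "images_per_class", 64),
      imageSize = pick(sy, "image_size", 32),
      difficulty = pick(sy, "difficulty", 0.2),
      seed = out$seed
    )
  }

  ber <- pick(cfg, "ber", list())
  out$berCfg <- berConfig(
    populationSize = pick(ber, "population_size", 5),
    iterations = pick(ber, "iterations", 5),
    explorationFraction = pick(ber, "exploration_fraction", 0.5),
    stagnationWindow = pick(ber, "stagnation_window", 3),
    stagnationTol = pick(ber, "stagnation_tol", 1e-9),
    seed = out$seed
  )
  coa <- pick(cfg, "coa", list())
  out$coaCfg <- coaConfig(
    populationSize = pick(coa, "population_size", 5),
    iterations = pick(coa, "iterations", 5),
    seed = out$seed
  )
  tr <- pick(cfg, "training", list())
  out$trialEpochs <- pick(tr, "trial_epochs", 5)
  out$finalEpochs <- pick(tr, "final_epochs", 15)
  out
}

#' Run the pipeline from a configuration file
#'
#' Executes [runFullPipeline()] once per configured split ratio, writing
#' artifacts under `<output_dir>/split_<ratio>`.
#'
#' @param path YAML configuration path (see [readRunConfig()]).
#' @return named list of pipeline results, one per split ratio,
#'   invisibly.
#' @export
runFromConfig <- function(path) {
  cfg <- readRunConfig(path)
  results <- list()
  for (ratio in cfg$splitRatios) {
    tag <- sprintf("split_%02d", round(ratio * 100))
    outDir <- if (is.null(cfg$outputDir)) NULL else {
      file.path(cfg$outputDir, tag)
    }
    results[[tag]] <- runFullPipeline(
      cfg$data, splitRatio = ratio, berCfg = cfg$berCfg,
      coaCfg = cfg$coaCfg, trialEpochs = cfg$trialEpochs,
      finalEpochs = cfg$finalEpochs, seed = cfg$seed, outDir = outDir
    )
  }
  invisible(results)
}
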