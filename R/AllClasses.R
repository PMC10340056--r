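#' @include utils.R
NULL

# ---- optimizer configurations ------------------------------------------

#' Configuration for the Al-Biruni Earth Radius optimizer
#'
#' @slot populationSize number of search agents.
#' @slot iterations iteration budget `N`.
#' @slot explorationFraction fraction of agents in the exploration
#'   subgroup (the rest exploit around the leader); each subgroup keeps at
#'   least one agent.
#' @slot stagnationWindow number of consecutive iterations without a
#'   best-fitness improvement before the mutation operator replaces the
#'   exploration subgroup (default 3).
#' @slot stagnationTol improvement below this counts as stagnation.
#' @slot seed integer RNG seed for the run.
#' @export
setClass("BERConfig",
  slots = c(
    populationSize = "integer",
    iterations = "integer",
    explorationFraction = "numeric",
    stagnationWindow = "integer",
    stagnationTol = "numeric",
    seed = "integer"
  )
)

setValidity("BERConfig", function(object) {
  msg <- character()
  if (object@populationSize < 2L) {
    msg <- c(msg, "populationSize must be >= 2")
  }
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  ef <- object@explorationFraction
  if (ef <= 0 || ef >= 1) {
    msg <- c(msg, "explorationFraction must lie in (0, 1)")
  } else {
    nExp <- round(ef * object@populationSize)
    if (nExp < 1L || object@populationSize - nExp < 1L) {
      msg <- c(msg, "each subgroup must contain at least one agent")
    }
  }
  if (object@stagnationWindow < 1L) {
    msg <- c(msg, "stagnationWindow must be >= 1")
  }
  if (object@stagnationTol < 0) msg <- c(msg, "stagnationTol must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a BER optimizer configuration
#'
#' @param populationSize number of agents.
#' @param iterations iteration budget.
#' @param explorationFraction fraction of agents exploring, in (0,1).
#' @param stagnationWindow iterations of stagnation before mutation fires.
#' @param stagnationTol minimum best-fitness improvement counted as
#'   progress.
#' @param seed integer RNG seed.
#' @return a [BERConfig-class] object.
#' @export
#' @examples
#' berConfig(populationSize = 10, iterations = 20, seed = 1)
berConfig <- function(populationSize = 20, iterations = 50,
                      explorationFraction = 0.5, stagnationWindow = 3,
                      stagnationTol = 1e-9, seed = 1) {
  new("BERConfig",
    populationSize = as.integer(populationSize),
    iterations = as.integer(iterations),
    explorationFraction = as.numeric(explorationFraction),
    stagnationWindow = as.integer(stagnationWindow),
    stagnationTol = as.numeric(stagnationTol),
    seed = as.integer(seed)
  )
}

#' Configuration for the Coati Optimization Algorithm
#'
#' @slot populationSize number of coatis (>= 2 so both halves are
#'   non-empty).
#' @slot iterations iteration budget `T`.
#' @slot seed integer RNG seed for the run.
#' @export
setClass("COAConfig",
  slots = c(
    populationSize = "integer",
    iterations = "integer",
    seed = "integer"
  )
)

setValidity("COAConfig", function(object) {
  msg <- character()
  if (floor(object@populationSize / 2) < 1) {
    msg <- c(msg, "populationSize must be >= 2 (both halves non-empty)")
  }
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a COA optimizer configuration
#'
#' @param populationSize number of coatis (>= 2).
#' @param iterations iteration budget.
#' @param seed integer RNG seed.
#' @return a [COAConfig-class] object.
#' @export
#' @examples
#' coaConfig(populationSize = 10, iterations = 20, seed = 1)
coaConfig <- function(populationSize = 20, iterations = 50, seed = 1) {
  new("COAConfig",
    populationSize = as.integer(populationSize),
    iterations = as.integer(iterations),
    seed = as.integer(seed)
  )
}

# ---- search space -------------------------------------------------------

#' A single hyperparameter dimension
#'
#' @slot name unique dimension name.
#' @slot kind `"continuous"`, `"integer"` or `"categorical"`.
#' @slot lower,upper numeric range (continuous/integer kinds).
#' @slot choices list of category values (categorical kind).
#' @slot scale `"linear"` or `"log"`; log scale needs a strictly positive
#'   range.
#' @export
setClass("HyperParam",
  slots = c(
    name = "character",
    kind = "character",
    lower = "numeric",
    upper = "numeric",
    choices = "list",
    scale = "character"
  )
)

setValidity("HyperParam", function(object) {
  msg <- character()
  if (!object@kind %in% c("continuous", "integer", "categorical")) {
    msg <- c(msg, "kind must be continuous, integer or categorical")
  }
  if (!object@scale %in% c("linear", "log")) {
    msg <- c(msg, "scale must be linear or log")
  }
  if (object@kind == "categorical") {
    if (length(object@choices) < 1L) {
      msg <- c(msg, "categorical dimension needs at least one choice")
    }
  } else {
    if (length(object@lower) != 1L || length(object@upper) != 1L ||
        !is.finite(object@lower) || !is.finite(object@upper) ||
        object@lower > object@upper) {
      msg <- c(msg, "invalid range")
    } else if (object@scale == "log" && object@lower <= 0) {
      msg <- c(msg, "log scale requires a strictly positive range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Define a hyperparameter dimension
#'
#' @param name dimension name.
#' @param kind `"continuous"`, `"integer"` or `"categorical"`.
#' @param lower,upper range for continuous/integer kinds.
#' @param choices vector or list of categorical values.
#' @param scale `"linear"` (default) or `"log"`.
#' @return a [HyperParam-class] object.
#' @export
#' @examples
#' hyperParam("lr", "continuous", 1e-4, 1e-1, scale = "log")
#' hyperParam("ecaKernel", "categorical", choices = c(3, 5, 7))
hyperParam <- function(name, kind, lower = NA_real_, upper = NA_real_,
                       choices = list(), scale = "linear") {
  new("HyperParam",
    name = as.character(name), kind = as.character(kind),
    lower = as.numeric(lower), upper = as.numeric(upper),
    choices = as.list(choices), scale = as.character(scale)
  )
}

#' An ordered hyperparameter search space
#'
#' Optimizers run on the unit box `[0,1]^d`; [decodeVector()] maps unit
#' coordinates into the physical ranges described here.
#'
#' @slot params list of [HyperParam-class] dimensions with unique names.
#' @export
setClass("SearchSpace", slots = c(params = "list"))

setValidity("SearchSpace", function(object) {
  if (!length(object@params)) return("search space is empty")
  if (!all(vapply(object@params, is, logical(1), "HyperParam"))) {
    return("all dimensions must be HyperParam objects")
  }
  nm <- vapply(object@params, function(p) p@name, character(1))
  if (anyDuplicated(nm)) return("dimension names must be unique")
  TRUE
})

#' Build a search space from hyperparameter dimensions
#'
#' @param ... [HyperParam-class] objects (or a single list of them).
#' @return a [SearchSpace-class] object.
#' @export
#' @examples
#' searchSpace(hyperParam("dropout", "continuous", 0, 0.6))
searchSpace <- function(...) {
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1L]]) &&
      !is(params[[1L]], "HyperParam")) {
    params <- params[[1L]]
  }
  new("SearchSpace", params = params)
}

#' @describeIn SearchSpace-class number of dimensions.
#' @param x a `SearchSpace`.
#' @export
setMethod("length", "SearchSpace", function(x) length(x@params))

#' @describeIn SearchSpace-class dimension names.
#' @export
setMethod("names", "SearchSpace", function(x) {
  vapply(x@params, function(p) p@name, character(1))
})

setMethod("show", "SearchSpace", function(object) {
  cat(sprintf("SearchSpace with %d dimension(s)\n", length(object)))
  for (p in object@params) {
    rng <- if (p@kind == "categorical") {
      paste0("{", paste(unlist(p@choices), collapse = ", "), "}")
    } else {
      sprintf("[%g, %g]%s", p@lower, p@upper,
              if (p@scale == "log") " (log)" else "")
    }
    cat(sprintf("  %-14s %-11s %s\n", p@name, p@kind, rng))
  }
  invisible(NULL)
})

# ---- data containers ----------------------------------------------------

#' A set of labelled RGB images
#'
#' Images are `height x width x 3` numeric arrays with integer values in
#' `[0, 255]`; labels are 1-based integers indexing `classNames`.
#'
#' @slot images list of RGB arrays.
#' @slot labels integer vector, same length as `images`.
#' @slot classNames ordered class names.
#' @export
setClass("LabeledImageSet",
  slots = c(
    images = "list",
    labels = "integer",
    classNames = "character"
  )
)

setValidity("LabeledImageSet", function(object) {
  msg <- character()
  if (length(object@images) != length(object@labels)) {
    msg <- c(msg, "images and labels differ in length")
  }
  k <- length(object@classNames)
  if (k < 1L) msg <- c(msg, "at least one class name is required")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > k)) {
    msg <- c(msg, "labels must index classNames (1-based)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImageSet
#'
#' @param images list of `H x W x 3` arrays with values in `[0, 255]`.
#' @param labels integer labels (1-based, indexing `classNames`).
#' @param classNames ordered class names.
#' @return a [LabeledImageSet-class] object.
#' @export
labeledImageSet <- function(images, labels, classNames) {
  new("LabeledImageSet",
    images = images, labels = as.integer(labels),
    classNames = as.character(classNames)
  )
}

#' @describeIn LabeledImageSet-class number of images.
#' @param x a `LabeledImageSet`.
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' Accessors for LabeledImageSet
#'
#' @param x a [LabeledImageSet-class] object.
#' @return `imageData()` the list of image arrays, `imageLabels()` the
#'   integer labels, `classNames()` the class-name vector.
#' @name LabeledImageSet-accessors
NULL

#' @rdname LabeledImageSet-accessors
#' @export
imageData <- function(x) x@images

#' @rdname LabeledImageSet-accessors
#' @export
imageLabels <- function(x) x@labels

#' @rdname LabeledImageSet-accessors
#' @export
classNames <- function(x) x@classNames

#' @describeIn LabeledImageSet-class subset by image index.
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledImageSet",
    images = x@images[i], labels = x@labels[i],
    classNames = x@classNames
  )
})

setMethod("show", "LabeledImageSet", function(object) {
  tab <- tabulate(object@labels, nbins = length(object@classNames))
  dims <- if (length(object@images)) {
    paste(dim(object@images[[1L]])[1:2], collapse = "x")
  } else "0x0"
  cat(sprintf("LabeledImageSet: %d image(s) (%s), %d class(es)\n",
              length(object@images), dims, length(object@classNames)))
  cat(paste(sprintf("  %s: %d", object@classNames, tab), collapse = "\n"),
      "\n")
  invisible(NULL)
})

#' Specification of a synthetic H&E-like dataset
#'
#' Each class is a distinct combination of base stain colour, nuclear blob
#' density/eccentricity, texture frequency and pixel noise. `difficulty`
#' interpolates every class parameter toward the across-class mean, so 0
#' is trivially separable and 1 collapses all classes.
#'
#' @slot nClasses number of classes.
#' @slot imagesPerClass images generated per class.
#' @slot imageSize square image side in pixels.
#' @slot difficulty separability control in `[0, 1]`.
#' @slot seed integer RNG seed.
#' @slot classParams list of per-class generative parameter lists.
#' @export
setClass("SyntheticSpec",
  slots = c(
    nClasses = "integer",
    imagesPerClass = "integer",
    imageSize = "integer",
    difficulty = "numeric",
    seed = "integer",
    classParams = "list"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@imagesPerClass < 1L) {
    msg <- c(msg, "imagesPerClass must be >= 1")
  }
  if (object@imageSize < 8L) msg <- c(msg, "imageSize must be >= 8")
  if (object@difficulty < 0 || object@difficulty > 1) {
    msg <- c(msg, "difficulty must lie in [0, 1]")
  }
  if (length(object@classParams) != object@nClasses) {
    msg <- c(msg, "classParams must have one entry per class")
  }
  if (object@difficulty < 1) {
    key <- vapply(object@classParams, function(p) {
      paste(c(p$baseColor, p$blobDensity, p$textureFreq), collapse = ",")
    }, character(1))
    if (anyDuplicated(key)) {
      msg <- c(msg, "class parameter sets must be pairwise distinct")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d classes x %d images, %dx%d px, difficulty %.2f\n",
    object@nClasses, object@imagesPerClass, object@imageSize,
    object@imageSize, object@difficulty
  ))
  invisible(NULL)
})

#' Per-class evaluation report
#'
#' Holds the Table-style metric block: one row per class with one-vs-rest
#' accuracy, precision, recall, F-score and AUC (all percent), plus an
#' unweighted macro-average row available through [reportTable()].
#'
#' @slot metrics numeric matrix, classes x 5 metric columns.
#' @slot flags logical matrix marking metric cells that were 0/0
#'   (reported as 0) or undefined AUC (reported as NA and skipped in the
#'   macro average).
#' @slot classNames row (class) names.
#' @slot split free-text split tag, e.g. `"80:20 test"`.
#' @export
setClass("EvaluationReport",
  slots = c(
    metrics = "matrix",
    flags = "matrix",
    classNames = "character",
    split = "character"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (ncol(object@metrics) != 5L) {
    msg <- c(msg, "metrics must have 5 columns")
  }
  if (nrow(object@metrics) != length(object@classNames)) {
    msg <- c(msg, "one metric row per class required")
  }
  ok <- object@metrics[is.finite(object@metrics)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 100)) {
    msg <- c(msg, "metrics must be percentages in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s)\n", object@split))
  print(round(reportTable(object), 2))
  invisible(NULL)
})
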