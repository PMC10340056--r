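#' @include AllClasses.R utils.R
NULL

#' Default per-class generative parameters
#'
#' Emulate H&E-stained tissue: a base stain colour (pink/purple
#' palette), Poisson-placed elliptical "nuclei", a band-limited texture
#' and Gaussian pixel noise. Class names follow the five lung/colon
#' histology categories.
#'
#' @return list of five class-parameter lists.
#' @export
defaultClassParams <- function() {
  list(
    list(name = "Col-Ad", baseColor = c(200, 140, 170),
         blobDensity = 0.012, blobEcc = 0.55, textureFreq = 6,
         noiseSd = 8),
    list(name = "Col-Be", baseColor = c(228, 180, 200),
         blobDensity = 0.004, blobEcc = 0.90, textureFreq = 3,
         noiseSd = 8),
    list(name = "Lun-Ad", baseColor = c(185, 150, 195),
         blobDensity = 0.010, blobEcc = 0.65, textureFreq = 8,
         noiseSd = 8),
    list(name = "Lun-Be", baseColor = c(235, 200, 215),
         blobDensity = 0.003, blobEcc = 0.85, textureFreq = 2,
         noiseSd = 8),
    list(name = "Lun-SC", baseColor = c(165, 120, 160),
         blobDensity = 0.015, blobEcc = 0.45, textureFreq = 10,
         noiseSd = 8)
  )
}

# interpolate every numeric class parameter toward the across-class mean;
# difficulty 0 keeps classes maximally distinct, 1 collapses them
applyDifficulty <- function(classParams, difficulty) {
  if (difficulty <= 0) return(classParams)
  fields <- c("baseColor", "blobDensity", "blobEcc", "textureFreq",
              "noiseSd")
  means <- lapply(fields, function(f) {
    Reduce(`+`, lapply(classParams, `[[`, f)) / length(classParams)
  })
  names(means) <- fields
  lapply(classParams, function(p) {
    for (f in fields) {
      p[[f]] <- (1 - difficulty) * p[[f]] + difficulty * means[[f]]
    }
    p
  })
}

#' Describe a synthetic histology-like dataset
#'
#' @param nClasses number of classes (default 5, the lung/colon set).
#' @param imagesPerClass images per class.
#' @param imageSize square image side in pixels.
#' @param difficulty separability control in `[0, 1]`: 0 keeps the
#'   default class palettes maximally distinct, larger values pull all
#'   class parameters toward their common mean.
#' @param seed integer RNG seed.
#' @param classParams optional list of per-class parameter lists (fields
#'   `name`, `baseColor`, `blobDensity`, `blobEcc`, `textureFreq`,
#'   `noiseSd`); defaults emulate the five lung/colon classes.
#' @return a [SyntheticSpec-class].
#' @export
#' @examples
#' syntheticSpec(imagesPerClass = 10, imageSize = 32, difficulty = 0.2)
syntheticSpec <- function(nClasses = 5, imagesPerClass = 100,
                          imageSize = 64, difficulty = 0, seed = 1,
                          classParams = NULL) {
  if (is.null(classParams)) {
    classParams <- defaultClassParams()[seq_len(nClasses)]
    if (nClasses > 5L) stop("supply classParams for more than 5 classes")
  }
  new("SyntheticSpec",
    nClasses = as.integer(nClasses),
    imagesPerClass = as.integer(imagesPerClass),
    imageSize = as.integer(imageSize),
    difficulty = as.numeric(difficulty),
    seed = as.integer(seed),
    classParams = classParams
  )
}

#' Generate one synthetic H&E-like image
#'
#' Draws a base-colour field, a Poisson number of elliptical nuclei
#' blobs (expected count `blobDensity * size^2`), an oriented band-limited
#' sinusoidal texture and Gaussian pixel noise, then rounds and clips to
#' integers in `[0, 255]`. Consumes the current RNG stream; seed it for
#' reproducibility. The realised blob count is attached as attribute
#' `"blobCount"`.
#'
#' @param params one class-parameter list (see [syntheticSpec()]).
#' @param size image side in pixels.
#' @return a `size x size x 3` integer-valued array.
#' @export
#' @examples
#' set.seed(1)
#' img <- generateClassImage(defaultClassParams()[[1]], size = 32)
#' dim(img)
generateClassImage <- function(params, size = 64) {
  img <- array(rep(params$baseColor, each = size * size),
               c(size, size, 3))
  xg <- matrix(rep(seq_len(size), each = size), size, size)
  yg <- matrix(rep(seq_len(size), times = size), size, size)

  nBlobs <- rpois(1, params$blobDensity * size^2)
  blobBase <- c(120, 60, 140) # hematoxylin-dark nuclear tone
  for (b in seq_len(nBlobs)) {
    cx <- runif(1, 1, size)
    cy <- runif(1, 1, size)
    theta <- runif(1, 0, pi)
    a <- runif(1, size / 24, size / 8)
    bb <- max(a * params$blobEcc, 0.5)
    u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
    v <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
    mask <- (u / a)^2 + (v / bb)^2 <= 1
    shade <- runif(1, 0.55, 0.8)
    col <- shade * blobBase + (1 - shade) * params$baseColor
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- 0.75 * col[ch] + 0.25 * plane[mask]
      img[, , ch] <- plane
    }
  }

  if (params$textureFreq > 0) {
    theta <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    tex <- 10 * sin(2 * pi * params$textureFreq *
                      (xg * cos(theta) + yg * sin(theta)) / size + phase)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tex * c(1, 0.8, 1)[ch]
  }

  if (params$noiseSd > 0) {
    img <- img + rnorm(length(img), sd = params$noiseSd)
  }
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "blobCount") <- nBlobs
  img
}

#' Generate a balanced synthetic dataset
#'
#' Deterministic for a given spec seed; classes are generated in order,
#' `imagesPerClass` each.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [LabeledImageSet-class].
#' @export
#' @examples
#' ds <- generateDataset(syntheticSpec(imagesPerClass = 3,
#'                                     imageSize = 16))
#' length(ds)
generateDataset <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  params <- applyDifficulty(spec@classParams, spec@difficulty)
  images <- vector("list", spec@nClasses * spec@imagesPerClass)
  labels <- integer(length(images))
  i <- 0L
  for (k in seq_len(spec@nClasses)) {
    for (j in seq_len(spec@imagesPerClass)) {
      i <- i + 1L
      images[[i]] <- generateClassImage(params[[k]], spec@imageSize)
      labels[i] <- k
    }
  }
  labeledImageSet(images, labels,
                  vapply(spec@classParams, `[[`, character(1), "name"))
}

#' Write a dataset as a class-per-folder image directory
#'
#' Creates `<root>/<class>/<class>_<i>.<ext>` files plus a `manifest.csv`
#' (path, class, label). PNG is lossless and round-trips pixel values
#' exactly; JPEG is supported for fidelity with public histology
#' archives.
#'
#' @param set a [LabeledImageSet-class].
#' @param root output directory (created if needed).
#' @param format `"png"` (default) or `"jpeg"`.
#' @param quality JPEG quality (ignored for PNG).
#' @return the root path, invisibly.
#' @export
writeDataset <- function(set, root, format = c("png", "jpeg"),
                         quality = 95) {
  format <- match.arg(format)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  counts <- integer(length(classNames(set)))
  rows <- vector("list", length(set))
  for (i in seq_along(set@images)) {
    k <- set@labels[i]
    cls <- set@classNames[k]
    dir.create(file.path(root, cls), showWarnings = FALSE)
    counts[k] <- counts[k] + 1L
    fn <- file.path(cls, sprintf("%s_%04d.%s", cls, counts[k], format))
    ebi <- EBImage::Image(aperm(set@images[[i]], c(2, 1, 3)) / 255,
                          colormode = "Color")
    EBImage::writeImage(ebi, file.path(root, fn), quality = quality)
    rows[[i]] <- data.frame(path = fn, class = cls, label = k)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(root)
}

#' Read a class-per-folder image directory
#'
#' Each subdirectory is a class; files are read as RGB with pixel values
#' rescaled to `[0, 255]`. When `classNames` is supplied, subdirectories
#' outside it are skipped with a warning; otherwise classes are the
#' sorted subdirectory names.
#'
#' @param root dataset directory.
#' @param classNames optional expected class names (sets label order).
#' @return a [LabeledImageSet-class].
#' @export
readDataset <- function(root, classNames = NULL) {
  if (!dir.exists(root)) stop("dataset root does not exist")
  dirs <- list.dirs(root, recursive = FALSE)
  if (!is.null(classNames)) {
    unknown <- dirs[!basename(dirs) %in% classNames]
    if (length(unknown)) {
      warning(sprintf("skipping unknown class folder(s): %s",
                      paste(basename(unknown), collapse = ", ")))
    }
    dirs <- file.path(root, classNames)
    dirs <- dirs[dir.exists(dirs)]
  } else {
    dirs <- dirs[order(basename(dirs))]
    classNames <- basename(dirs)
  }
  if (!length(dirs)) stop("no class folders found under the root")
  images <- list()
  labels <- integer()
  for (k in seq_along(dirs)) {
    files <- list.files(dirs[k], pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
    for (f in sort(files)) {
      ebi <- EBImage::readImage(f)
      arr <- aperm(as.array(ebi), c(2, 1, 3)) * 255
      images[[length(images) + 1L]] <- round(arr)
      labels <- c(labels, k)
    }
  }
  if (!length(images)) stop("no images found under the root")
  labeledImageSet(images, labels, classNames)
}

#' Stratified train/test split
#'
#' Splits each class independently at the requested fraction (rounded to
#' the nearest integer per class), so per-class proportions are
#' preserved; train and test are disjoint and their union is the input.
#' Deterministic for a given seed.
#'
#' @param set a [LabeledImageSet-class].
#' @param trainFraction fraction in (0, 1) assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test` [LabeledImageSet-class]s.
#' @export
#' @examples
#' ds <- generateDataset(syntheticSpec(imagesPerClass = 10,
#'                                     imageSize = 16))
#' sp <- splitDataset(ds, 0.8, seed = 1)
#' length(sp$train)
splitDataset <- function(set, trainFraction, seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  set.seed(deriveSeed(seed, "split"))
  trainIdx <- integer()
  for (k in seq_along(classNames(set))) {
    idx <- which(set@labels == k)
    if (length(idx) && length(idx) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 images",
                   set@classNames[k]))
    }
    nTrain <- min(length(idx) - 1L,
                  max(1L, roundHalfAway(trainFraction * length(idx))))
    trainIdx <- c(trainIdx, sample(idx, nTrain))
  }
  testIdx <- setdiff(seq_along(set@labels), trainIdx)
  list(train = set[sort(trainIdx)], test = set[sort(testIdx)])
}
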