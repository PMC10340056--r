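#' @include AllClasses.R nn-engine.R nn-ops.R
NULL

#' Configuration of the lightweight feature extractor
#'
#' @slot stageWidths channel width of each stage (every width divisible
#'   by `groups`); a 2x2 max-pool halves the resolution after each stage.
#' @slot groups channel-shuffle group count.
#' @slot ecaKernel odd 1D-convolution length of the ECA module.
#' @slot inputSize square input side in pixels.
#' @slot seed integer seed for weight initialisation.
#' @export
setClass("ExtractorConfig",
  slots = c(
    stageWidths = "integer",
    groups = "integer",
    ecaKernel = "integer",
    inputSize = "integer",
    seed = "integer"
  )
)

setValidity("ExtractorConfig", function(object) {
  msg <- character()
  if (!length(object@stageWidths) || any(object@stageWidths < 1L)) {
    msg <- c(msg, "stageWidths must be positive")
  }
  if (any(object@stageWidths %% object@groups != 0L)) {
    msg <- c(msg, "every stage width must be divisible by groups")
  }
  if (object@ecaKernel %% 2L == 0L) {
    msg <- c(msg, "ecaKernel must be odd")
  }
  if (any(object@ecaKernel > object@stageWidths)) {
    msg <- c(msg, "ecaKernel must not exceed any stage width")
  }
  if (object@inputSize %% 2^length(object@stageWidths) != 0L) {
    msg <- c(msg, "inputSize must be divisible by 2^(number of stages)")
  }
  if (length(msg)) msg else TRUE
})

#' Create an extractor configuration
#'
#' @param stageWidths integer vector of per-stage channel widths.
#' @param groups shuffle groups (must divide every width).
#' @param ecaKernel odd ECA kernel length.
#' @param inputSize input image side (divisible by `2^nStages`).
#' @param seed integer weight-initialisation seed.
#' @return an [ExtractorConfig-class].
#' @export
#' @examples
#' extractorConfig(stageWidths = c(8, 16), inputSize = 32)
extractorConfig <- function(stageWidths = c(8L, 16L), groups = 2L,
                            ecaKernel = 3L, inputSize = 64L, seed = 1L) {
  new("ExtractorConfig",
    stageWidths = as.integer(stageWidths), groups = as.integer(groups),
    ecaKernel = as.integer(ecaKernel), inputSize = as.integer(inputSize),
    seed = as.integer(seed)
  )
}

#' Build the depthwise-separable + ECA feature extractor
#'
#' Stacks one unit per stage: 1x1 pointwise convolution, channel shuffle,
#' depthwise 3x3 convolution, 1x1 pointwise convolution, and an ECA
#' module, followed by a 2x2 max-pool between stages. Weights are
#' He-initialised from the configuration seed and held fixed: the
#' extractor acts as a random convolutional feature map whose
#' architectural hyperparameters (widths, ECA kernel) are what the BER
#' search tunes.
#'
#' @param config an [ExtractorConfig-class].
#' @return an extractor handle (list with `config` and `params`).
#' @export
#' @examples
#' ext <- buildExtractor(extractorConfig(stageWidths = c(4, 8),
#'                                       inputSize = 16))
buildExtractor <- function(config) {
  validObject(config)
  set.seed(config@seed)
  widths <- config@stageWidths
  cin <- 3L
  params <- vector("list", length(widths))
  for (s in seq_along(widths)) {
    cout <- widths[s]
    params[[s]] <- list(
      pw1 = heInit(c(cin, cout), cin),
      b1 = numeric(cout),
      dw = heInit(c(3L, 3L, cout), 9),
      pw2 = heInit(c(cout, cout), cout),
      b2 = numeric(cout),
      eca = rnorm(config@ecaKernel, sd = 0.5)
    )
    cin <- cout
  }
  structure(list(config = config, params = params),
            class = "histoExtractor")
}

# batched pointwise (1x1) convolution: x is H x W x Cin x B
pointwiseApply <- function(x, w, b) {
  dm <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(dm[1] * dm[2] * dm[4], dm[3])
  out <- sweep(xm %*% w, 2L, b, "+")
  y <- array(out, c(dm[1], dm[2], dm[4], ncol(w)))
  aperm(y, c(1L, 2L, 4L, 3L))
}

# batched depthwise 3x3, same padding, stride 1
depthwiseApply <- function(x, k) {
  dm <- dim(x)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  xp <- array(0, c(H + 2L, W + 2L, C, B))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  g <- array(0, dm)
  for (dh in 1:3) {
    for (dj in 1:3) {
      sl <- xp[dh:(dh + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      g <- g + sweep(sl, 3L, k[dh, dj, ], "*")
    }
  }
  g
}

# batched ECA: per-image channel attention
ecaApply <- function(x, w) {
  dm <- dim(x)
  C <- dm[3]; B <- dm[4]
  xm <- x
  dim(xm) <- c(dm[1] * dm[2], C * B)
  favg <- matrix(colMeans(xm), C, B)
  s <- apply(favg, 2L, conv1dSame, w = w)
  s <- matrix(s, C, B)
  mc <- stableSigmoid(s)
  x * rep(as.vector(mc), each = dm[1] * dm[2])
}

#' Forward pass of the feature extractor
#'
#' @param extractor handle from [buildExtractor()].
#' @param x batched input tensor `H x W x 3 x B`, values already
#'   normalised (the training routines use `x/255 - 0.5`).
#' @return the final feature map, `H' x W' x C x B`.
#' @export
extractorForward <- function(extractor, x) {
  for (p in extractor$params) {
    x <- pointwiseApply(x, p$pw1, p$b1)
    x <- x * (x > 0)
    perm <- shufflePermutation(dim(x)[3], extractor$config@groups)
    x <- x[, , perm, , drop = FALSE]
    x <- depthwiseApply(x, p$dw)
    x <- x * (x > 0)
    x <- pointwiseApply(x, p$pw2, p$b2)
    x <- x * (x > 0)
    x <- ecaApply(x, p$eca)
    x <- poolForward(x)$out
  }
  x
}

#' Number of trainable-scale parameters in the extractor
#'
#' Counts the weights of the separable units; with the same stage
#' topology built from standard (non-separable) 3x3 convolutions the
#' count is strictly larger, which is the point of the separable design.
#'
#' @param extractor handle from [buildExtractor()].
#' @return integer parameter count.
#' @export
extractorParamCount <- function(extractor) {
  sum(vapply(extractor$params, function(p) {
    length(p$pw1) + length(p$b1) + length(p$dw) + length(p$pw2) +
      length(p$b2) + length(p$eca)
  }, numeric(1)))
}
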