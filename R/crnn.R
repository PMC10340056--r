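#' @include AllClasses.R nn-engine.R extractor.R
NULL

#' Configuration of the convolutional-recurrent classifier head
#'
#' Conv blocks use 3x3 kernels, ReLU, 2x2/stride-2 max-pooling, batch
#' normalisation and dropout; the resulting feature map is read as a
#' sequence along the width axis (one timestep per column, features =
#' height x channels), passed through an LSTM, a 64-neuron fully
#' connected layer and a softmax over the classes.
#'
#' @slot convWidths filter counts of the conv blocks.
#' @slot dropout dropout rate in `[0, 1)`.
#' @slot lstmUnits LSTM hidden size.
#' @slot fcUnits fully connected width (64 by construction).
#' @slot nClasses number of output classes.
#' @slot labelSmoothing smoothing mass `eps` in `[0, 0.5)`; 0 gives plain
#'   cross-entropy.
#' @slot seed integer weight-initialisation seed.
#' @export
setClass("CRNNConfig",
  slots = c(
    convWidths = "integer",
    dropout = "numeric",
    lstmUnits = "integer",
    fcUnits = "integer",
    nClasses = "integer",
    labelSmoothing = "numeric",
    seed = "integer"
  )
)

setValidity("CRNNConfig", function(object) {
  msg <- character()
  if (!length(object@convWidths) || any(object@convWidths < 1L)) {
    msg <- c(msg, "convWidths must be positive")
  }
  if (object@dropout < 0 || object@dropout >= 1) {
    msg <- c(msg, "dropout must lie in [0, 1)")
  }
  if (object@lstmUnits < 1L) msg <- c(msg, "lstmUnits must be >= 1")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@labelSmoothing < 0 || object@labelSmoothing >= 0.5) {
    msg <- c(msg, "labelSmoothing must lie in [0, 0.5)")
  }
  if (length(msg)) msg else TRUE
})

#' Create a CRNN head configuration
#'
#' @param convWidths integer vector of conv-block filter counts.
#' @param dropout dropout rate in `[0, 1)`.
#' @param lstmUnits LSTM hidden size.
#' @param nClasses number of classes.
#' @param labelSmoothing smoothing mass in `[0, 0.5)`.
#' @param seed weight-initialisation seed.
#' @return a [CRNNConfig-class].
#' @export
#' @examples
#' crnnConfig(lstmUnits = 32, nClasses = 5)
crnnConfig <- function(convWidths = 16L, dropout = 0.2, lstmUnits = 32L,
                       nClasses = 5L, labelSmoothing = 0.1, seed = 1L) {
  new("CRNNConfig",
    convWidths = as.integer(convWidths), dropout = as.numeric(dropout),
    lstmUnits = as.integer(lstmUnits), fcUnits = 64L,
    nClasses = as.integer(nClasses),
    labelSmoothing = as.numeric(labelSmoothing), seed = as.integer(seed)
  )
}

#' Build the convolutional-recurrent classifier head
#'
#' @param config a [CRNNConfig-class].
#' @param inputShape integer `c(H, W, C)` of the incoming feature map
#'   (the extractor output).
#' @return a model handle (list with `config`, `inputShape`, `params`,
#'   `running` batch-norm statistics).
#' @export
buildCRNN <- function(config, inputShape) {
  validObject(config)
  stopifnot(length(inputShape) == 3L)
  nb <- length(config@convWidths)
  if (inputShape[1] %% 2^nb != 0L || inputShape[2] %% 2^nb != 0L) {
    stop("input too small or odd-sized for the configured pooling depth")
  }
  set.seed(config@seed)
  params <- list()
  running <- list()
  cin <- inputShape[3]
  h <- inputShape[1]; w <- inputShape[2]
  for (s in seq_len(nb)) {
    cout <- config@convWidths[s]
    params[[paste0("convW", s)]] <- heInit(c(3L, 3L, cin, cout),
                                           9 * cin)
    params[[paste0("convB", s)]] <- numeric(cout)
    params[[paste0("gamma", s)]] <- rep(1, cout)
    params[[paste0("beta", s)]] <- numeric(cout)
    running[[s]] <- list(mean = numeric(cout), var = rep(1, cout))
    cin <- cout
    h <- h %/% 2L; w <- w %/% 2L
  }
  p <- h * cin # timestep feature size
  u <- config@lstmUnits
  params$lstmWx <- matrix(rnorm(4L * u * p, sd = sqrt(1 / p)), 4L * u, p)
  params$lstmWh <- matrix(rnorm(4L * u * u, sd = sqrt(1 / u)), 4L * u, u)
  params$lstmB <- numeric(4L * u)
  params$fcW <- matrix(rnorm(config@fcUnits * u, sd = sqrt(2 / u)),
                       config@fcUnits, u)
  params$fcB <- numeric(config@fcUnits)
  params$outW <- matrix(rnorm(config@nClasses * config@fcUnits,
                              sd = sqrt(2 / config@fcUnits)),
                        config@nClasses, config@fcUnits)
  params$outB <- numeric(config@nClasses)
  structure(list(config = config, inputShape = as.integer(inputShape),
                 params = params, running = running),
            class = "histoCRNN")
}

# forward pass; training = TRUE uses batch statistics and dropout and
# returns layer caches for the backward pass
crnnForward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  nb <- length(cfg@convWidths)
  caches <- list(blocks = vector("list", nb))
  for (s in seq_len(nb)) {
    cv <- convForward(x, p[[paste0("convW", s)]], p[[paste0("convB", s)]])
    rl <- reluForward(cv$out)
    pl <- poolForward(rl$out)
    bn <- bnForward(pl$out, p[[paste0("gamma", s)]],
                    p[[paste0("beta", s)]], model$running[[s]],
                    training = training)
    if (training) model$running[[s]] <- bn$running
    dr <- dropForward(bn$out, cfg@dropout, training)
    caches$blocks[[s]] <- list(conv = cv$cache, relu = rl$cache,
                               pool = pl$cache, bn = bn$cache,
                               drop = dr$cache)
    x <- dr$out
  }
  caches$mapDims <- dim(x)
  xs <- mapToSequence(x)
  lf <- lstmForward(xs, p$lstmWx, p$lstmWh, p$lstmB)
  caches$lstm <- lf$cache
  fc <- denseForward(lf$out, p$fcW, p$fcB)
  fr <- reluForward(fc$out)
  caches$fc <- fc$cache
  caches$fcRelu <- fr$cache
  out <- denseForward(fr$out, p$outW, p$outB)
  caches$out <- out$cache
  list(logits = out$out, caches = caches, model = model)
}

# backward pass; returns gradients named like the parameters
crnnBackward <- function(model, caches, dlogits) {
  p <- model$params
  g <- list()
  ob <- denseBackward(dlogits, p$outW, caches$out)
  g$outW <- ob$dw; g$outB <- ob$db
  dfc <- reluBackward(ob$dx, caches$fcRelu)
  fb <- denseBackward(dfc, p$fcW, caches$fc)
  g$fcW <- fb$dw; g$fcB <- fb$db
  lb <- lstmBackward(fb$dx, p$lstmWx, p$lstmWh, caches$lstm)
  g$lstmWx <- lb$dwx; g$lstmWh <- lb$dwh; g$lstmB <- lb$db
  dx <- sequenceGradToMap(lb$dxs, caches$mapDims)
  for (s in rev(seq_along(caches$blocks))) {
    blk <- caches$blocks[[s]]
    dx <- dropBackward(dx, blk$drop)
    bb <- bnBackward(dx, blk$bn)
    g[[paste0("gamma", s)]] <- bb$dgamma
    g[[paste0("beta", s)]] <- bb$dbeta
    dx <- poolBackward(bb$dx, blk$pool)
    dx <- reluBackward(dx, blk$relu)
    cb <- convBackward(dx, blk$conv)
    g[[paste0("convW", s)]] <- cb$dw
    g[[paste0("convB", s)]] <- cb$db
    dx <- cb$dx
  }
  g
}

# stack a list of H x W x 3 images (0..255) into a normalised batch
imagesToBatch <- function(images) {
  dm <- dim(images[[1L]])
  x <- array(0, c(dm[1], dm[2], dm[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x / 255 - 0.5
}

#' Train the classifier head on extractor features
#'
#' Minimises label-smoothing cross-entropy with Adam over the CRNN head
#' parameters; the extractor supplies fixed convolutional features
#' (computed once per call). Deterministic for a given `seed`.
#'
#' @param extractor handle from [buildExtractor()] (or `NULL` when
#'   `trainFeatures`/`valFeatures` are supplied directly).
#' @param crnn handle from [buildCRNN()].
#' @param trainSet,valSet [LabeledImageSet-class] objects; `valSet` may
#'   be `NULL`.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param weightDecay L2 penalty added to the gradients.
#' @param seed integer seed controlling shuffling and dropout.
#' @param trainFeatures,valFeatures optional precomputed feature tensors
#'   (`H x W x C x B`), bypassing the extractor forward pass.
#' @return list with the trained `model` and a per-epoch `history` data
#'   frame (train/val loss and error rate).
#' @export
trainClassifier <- function(extractor, crnn, trainSet, valSet = NULL,
                            epochs = 5, batchSize = 16, lr = 1e-3,
                            weightDecay = 1e-5, seed = 1,
                            trainFeatures = NULL, valFeatures = NULL) {
  if (is.null(trainFeatures)) {
    if (length(trainSet) == 0L) stop("training set is empty")
    trainFeatures <- extractorForward(extractor,
                                      imagesToBatch(imageData(trainSet)))
  }
  yTrain <- imageLabels(trainSet)
  if (is.null(valFeatures) && !is.null(valSet) && length(valSet)) {
    valFeatures <- extractorForward(extractor,
                                    imagesToBatch(imageData(valSet)))
  }
  yVal <- if (!is.null(valSet)) imageLabels(valSet) else NULL
  if (any(yTrain < 1L) || any(yTrain > crnn$config@nClasses)) {
    stop("labels outside [1, nClasses]")
  }

  set.seed(deriveSeed(seed, "train"))
  n <- length(yTrain)
  eps <- crnn$config@labelSmoothing
  adam <- adamInit(crnn$params)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_, train_error = NA_real_,
                        val_error = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      xb <- trainFeatures[, , , idx, drop = FALSE]
      fw <- crnnForward(crnn, xb, training = TRUE)
      crnn <- fw$model
      lg <- smoothedLossGrad(fw$logits, yTrain[idx], eps)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training aborted: non-finite loss at epoch %d", ep))
      }
      losses <- c(losses, lg$loss)
      grads <- crnnBackward(crnn, fw$caches, lg$dlogits)
      upd <- adamStep(crnn$params, grads, adam, lr, weightDecay)
      crnn$params <- upd$params
      adam <- upd$state
    }
    history$train_loss[ep] <- mean(losses)
    trEval <- evalOnFeatures(crnn, trainFeatures, yTrain)
    history$train_error[ep] <- trEval$error
    if (!is.null(yVal)) {
      vEval <- evalOnFeatures(crnn, valFeatures, yVal)
      history$val_loss[ep] <- vEval$loss
      history$val_error[ep] <- vEval$error
    }
  }
  list(model = crnn, history = history)
}

# evaluation-mode loss/error on a feature tensor
evalOnFeatures <- function(crnn, features, labels) {
  fw <- crnnForward(crnn, features, training = FALSE)
  lg <- smoothedLossGrad(fw$logits, labels, crnn$config@labelSmoothing)
  pred <- apply(lg$probs, 2L, which.max)
  list(loss = lg$loss, error = 100 * mean(pred != labels),
       probs = t(lg$probs))
}

#' Predict class probabilities
#'
#' @param extractor handle from [buildExtractor()].
#' @param crnn trained handle from [trainClassifier()].
#' @param images list of `H x W x 3` arrays (0..255) or a
#'   [LabeledImageSet-class].
#' @return numeric matrix, one row per image, one column per class; rows
#'   sum to 1.
#' @export
predictProba <- function(extractor, crnn, images) {
  if (is(images, "LabeledImageSet")) images <- imageData(images)
  x <- imagesToBatch(images)
  if (dim(x)[1] != extractor$config@inputSize) {
    stop("images do not match the configured input size")
  }
  feats <- extractorForward(extractor, x)
  fw <- crnnForward(crnn, feats, training = FALSE)
  t(softmaxProbs(fw$logits))
}

#' Predict class labels
#'
#' @inheritParams predictProba
#' @return integer labels (1-based argmax of [predictProba()]).
#' @export
predictClasses <- function(extractor, crnn, images) {
  apply(predictProba(extractor, crnn, images), 1L, which.max)
}

#' Save / load a tuned model checkpoint
#'
#' Checkpoints use R's standard serialisation (RDS) and bundle the
#' extractor and head handles.
#'
#' @param extractor,crnn model handles.
#' @param path checkpoint path.
#' @return `saveModel()` the path invisibly; `loadModel()` a list with
#'   `extractor` and `crnn`.
#' @export
saveModel <- function(extractor, crnn, path) {
  saveRDS(list(extractor = extractor, crnn = crnn), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
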