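#' @include utils.R
NULL

# Internal mini neural-network engine. Batched tensors are H x W x C x B
# numeric arrays (sample index last). Convolutions use im2col plus a
# single BLAS matrix multiply; every layer has a matching backward pass
# verified against central finite differences in the test suite.

heInit <- function(dims, fanIn) {
  array(rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
}

# ---- 2D convolution, same padding, stride 1 ----------------------------

im2col <- function(xp, H, W, Cin, B, kh, kw) {
  nOut <- H * W * B
  cols <- matrix(0, nOut, kh * kw * Cin)
  idx <- 1L
  for (dh in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      sl <- xp[dh:(dh + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      sl <- aperm(sl, c(1L, 2L, 4L, 3L))
      dim(sl) <- c(nOut, Cin)
      cols[, idx:(idx + Cin - 1L)] <- sl
      idx <- idx + Cin
    }
  }
  cols
}

convWeightMatrix <- function(w) {
  kd <- dim(w)
  kh <- kd[1]; kw <- kd[2]; Cin <- kd[3]; nf <- kd[4]
  wmat <- matrix(0, kh * kw * Cin, nf)
  idx <- 1L
  for (dh in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      wmat[idx:(idx + Cin - 1L), ] <- matrix(w[dh, dj, , ], Cin, nf)
      idx <- idx + Cin
    }
  }
  wmat
}

convForward <- function(x, w, b) {
  dm <- dim(x)
  H <- dm[1]; W <- dm[2]; Cin <- dm[3]; B <- dm[4]
  kd <- dim(w)
  kh <- kd[1]; kw <- kd[2]; nf <- kd[4]
  stopifnot(kd[3] == Cin, kh %% 2L == 1L, kw %% 2L == 1L)
  p <- (kh - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, Cin, B))
  xp[(p + 1L):(p + H), (p + 1L):(p + W), , ] <- x
  cols <- im2col(xp, H, W, Cin, B, kh, kw)
  wmat <- convWeightMatrix(w)
  out <- sweep(cols %*% wmat, 2L, b, "+")
  y <- array(out, c(H, W, B, nf))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  list(out = y,
       cache = list(cols = cols, wmat = wmat, dims = dm, kdims = kd,
                    pad = p))
}

convBackward <- function(dy, cache) {
  dm <- cache$dims
  H <- dm[1]; W <- dm[2]; Cin <- dm[3]; B <- dm[4]
  kd <- cache$kdims
  kh <- kd[1]; kw <- kd[2]; nf <- kd[4]
  p <- cache$pad
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(H * W * B, nf)
  db <- colSums(dym)
  dwmat <- crossprod(cache$cols, dym)
  dw <- array(0, kd)
  idx <- 1L
  for (dh in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      dw[dh, dj, , ] <- array(dwmat[idx:(idx + Cin - 1L), ], c(Cin, nf))
      idx <- idx + Cin
    }
  }
  dcols <- dym %*% t(cache$wmat)
  dxp <- array(0, c(H + 2L * p, W + 2L * p, Cin, B))
  idx <- 1L
  for (dh in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      blk <- dcols[, idx:(idx + Cin - 1L), drop = FALSE]
      dim(blk) <- c(H, W, B, Cin)
      blk <- aperm(blk, c(1L, 2L, 4L, 3L))
      dxp[dh:(dh + H - 1L), dj:(dj + W - 1L), , ] <-
        dxp[dh:(dh + H - 1L), dj:(dj + W - 1L), , , drop = FALSE] + blk
      idx <- idx + Cin
    }
  }
  dx <- dxp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# ---- ReLU ---------------------------------------------------------------

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

reluBackward <- function(dy, cache) dy * cache

# ---- 2x2 max pooling, stride 2 -----------------------------------------

poolForward <- function(x) {
  dm <- dim(x)
  H <- dm[1]; W <- dm[2]
  if (H %% 2L != 0L || W %% 2L != 0L) {
    stop("feature map too small or odd-sized for 2x2 pooling")
  }
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- x[i1, j1, , , drop = FALSE]
  b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]
  d <- x[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, d)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = y, cache = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4,
                             dims = dm))
}

poolBackward <- function(dy, cache) {
  dm <- cache$dims
  H <- dm[1]; W <- dm[2]
  dx <- array(0, dm)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  dx[i1, j1, , ] <- dy * cache$m1
  dx[i2, j1, , ] <- dy * cache$m2
  dx[i1, j2, , ] <- dy * cache$m3
  dx[i2, j2, , ] <- dy * cache$m4
  dx
}

# ---- batch normalisation (per channel) ---------------------------------

bnForward <- function(x, gamma, beta, running, momentum = 0.9,
                      eps = 1e-5, training = TRUE) {
  dm <- dim(x)
  C <- dm[3]
  m <- prod(dm[-3])
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  y <- array(ym, c(dm[1], dm[2], dm[4], C))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  list(out = y, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    dims = dm))
}

bnBackward <- function(dy, cache) {
  dm <- cache$dims
  C <- dm[3]
  m <- prod(dm[-3])
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(m, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  centred <- sweep(dym, 2L, colMeans(dym)) -
    sweep(xhat, 2L, colMeans(dym * xhat), "*")
  dxm <- sweep(centred, 2L, cache$gamma * cache$invstd, "*")
  dx <- array(dxm, c(dm[1], dm[2], dm[4], C))
  dx <- aperm(dx, c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- inverted dropout ---------------------------------------------------

dropForward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropBackward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- feature map <-> width-axis sequence -------------------------------

# each column of the feature map becomes one timestep; the feature vector
# stacks height x channels
mapToSequence <- function(x) {
  dm <- dim(x)
  lapply(seq_len(dm[2]), function(w) {
    sl <- x[, w, , , drop = FALSE]
    dim(sl) <- c(dm[1] * dm[3], dm[4])
    sl
  })
}

sequenceGradToMap <- function(dxs, dims) {
  dx <- array(0, dims)
  for (w in seq_along(dxs)) {
    blk <- dxs[[w]]
    dim(blk) <- c(dims[1], dims[3], dims[4])
    dx[, w, , ] <- blk
  }
  dx
}

# ---- LSTM (last-hidden-state readout) ----------------------------------

lstmForward <- function(xs, wx, wh, b) {
  u <- ncol(wh)
  B <- ncol(xs[[1L]])
  h <- matrix(0, u, B)
  cc <- matrix(0, u, B)
  Tn <- length(xs)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- wx %*% xs[[t]] + wh %*% h + b
    i <- stableSigmoid(z[1:u, , drop = FALSE])
    f <- stableSigmoid(z[(u + 1L):(2L * u), , drop = FALSE])
    g <- tanh(z[(2L * u + 1L):(3L * u), , drop = FALSE])
    o <- stableSigmoid(z[(3L * u + 1L):(4L * u), , drop = FALSE])
    cPrev <- cc
    hPrev <- h
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = cPrev,
                       hPrev = hPrev, tc = tc, x = xs[[t]])
  }
  list(out = h, cache = cache)
}

lstmBackward <- function(dh, wx, wh, cache) {
  Tn <- length(cache)
  dwx <- matrix(0, nrow(wx), ncol(wx))
  dwh <- matrix(0, nrow(wh), ncol(wh))
  db <- numeric(nrow(wx))
  dxs <- vector("list", Tn)
  dc <- matrix(0, nrow(dh), ncol(dh))
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    do <- dh * cc$tc
    dct <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dct * cc$g
    df <- dct * cc$cPrev
    dg <- dct * cc$i
    dc <- dct * cc$f
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dwx <- dwx + tcrossprod(dz, cc$x)
    dwh <- dwh + tcrossprod(dz, cc$hPrev)
    db <- db + rowSums(dz)
    dxs[[t]] <- crossprod(wx, dz)
    dh <- crossprod(wh, dz)
  }
  list(dxs = dxs, dwx = dwx, dwh = dwh, db = db)
}

# ---- dense --------------------------------------------------------------

denseForward <- function(x, w, b) {
  list(out = w %*% x + b, cache = x)
}

denseBackward <- function(dy, w, cache) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, cache),
       db = rowSums(dy))
}

# ---- softmax / label-smoothing cross-entropy ---------------------------

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# labels 1-based; eps = 0 reduces to plain cross-entropy
smoothedLossGrad <- function(logits, labels, eps) {
  nClasses <- nrow(logits)
  B <- ncol(logits)
  p <- softmaxProbs(logits)
  y <- matrix(eps / nClasses, nClasses, B)
  hit <- cbind(labels, seq_len(B))
  y[hit] <- y[hit] + (1 - eps)
  loss <- -mean(colSums(y * log(pmax(p, 1e-12))))
  list(loss = loss, dlogits = (p - y) / B, probs = p)
}

# ---- Adam ---------------------------------------------------------------

adamInit <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adamStep <- function(params, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
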