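# Independent oracles used across the suite. These deliberately re-derive
# every quantity with naive scalar arithmetic (per-equation loops, nested
# summations) so they share no code path with the package internals; the
# optimizer transcriptions replay the package's documented random-draw
# order so both sides can be fed the identical RNG stream.

oracleClip <- function(v, lower, upper) pmin(pmax(v, lower), upper)

# replicate the package's angle draw (uniform on (0,180), vector-level
# resampling of entries too close to x = 0)
oracleDrawAngle <- function(n) {
  x <- runif(n, 0, 180)
  repeat {
    bad <- abs(1 - cos(x * pi / 180)) <= 1e-12
    if (!any(bad)) return(x)
    x[bad] <- runif(sum(bad), 0, 180)
  }
}

oracleRadius <- function(h, xDeg) {
  cx <- cos(xDeg * pi / 180)
  h * cx / (1 - cx)
}

# one full BER iteration, transcribed equation by equation
oracleBERIterate <- function(agents, fit, best, bestF, t, N, nExplore,
                             stagnation, window, tol, lower, upper,
                             fitness) {
  d <- ncol(agents)
  P <- nrow(agents)
  bestBefore <- bestF
  accept <- function(i, cand) {
    f <- fitness(cand)
    if (f < fit[i]) {
      agents[i, ] <<- cand
      fit[i] <<- f
      if (f < bestF) {
        best <<- cand
        bestF <<- f
      }
    }
  }
  for (i in seq_len(nExplore)) {
    S <- agents[i, ]
    r1 <- runif(d)
    r2 <- runif(d)
    cand <- numeric(d)
    for (j in seq_len(d)) {
      Dj <- r1[j] * (S[j] - 1)
      cand[j] <- S[j] + Dj * (2 * r2[j] - 1)
    }
    accept(i, oracleClip(cand, lower, upper))
  }
  for (i in seq.int(nExplore + 1, P)) {
    u <- runif(1)
    S <- agents[i, ]
    cand <- numeric(d)
    if (u < 0.5) {
      r3 <- runif(d)
      r2 <- runif(d)
      for (j in seq_len(d)) {
        Dj <- r3[j] * (best[j] - S[j])
        cand[j] <- r2[j] * (S[j] + Dj)
      }
    } else {
      z <- runif(1)
      h <- runif(1, 0, 2)
      x <- oracleDrawAngle(1)
      r <- oracleRadius(h, x)
      k <- z + 2 * t^2 / N^2
      for (j in seq_len(d)) cand[j] <- r * (best[j] + k)
    }
    accept(i, oracleClip(cand, lower, upper))
  }
  if (bestBefore - bestF < tol) {
    stagnation <- stagnation + 1
  } else {
    stagnation <- 0
  }
  mutated <- FALSE
  if (stagnation >= window) {
    for (i in seq_len(nExplore)) {
      z <- runif(d)
      h <- runif(d, 0, 2)
      x <- oracleDrawAngle(d)
      cand <- numeric(d)
      for (j in seq_len(d)) {
        k <- z[j] + 2 * t^2 / N^2
        cand[j] <- k * z[j]^2 - oracleRadius(h[j], x[j])
      }
      cand <- oracleClip(cand, lower, upper)
      f <- fitness(cand)
      agents[i, ] <- cand
      fit[i] <- f
      if (f < bestF) {
        best <- cand
        bestF <- f
      }
    }
    stagnation <- 0
    mutated <- TRUE
  }
  list(agents = agents, fit = fit, best = best, bestF = bestF,
       stagnation = stagnation, mutated = mutated)
}

# one full COA iteration, transcribed equation by equation
oracleCOAIterate <- function(agents, fit, best, bestF, t, lower, upper,
                             fitness) {
  d <- ncol(agents)
  P <- nrow(agents)
  half <- floor(P / 2)
  accept <- function(i, cand) {
    f <- fitness(cand)
    if (f < fit[i]) {
      agents[i, ] <<- cand
      fit[i] <<- f
      if (f < bestF) {
        best <<- cand
        bestF <<- f
      }
    }
  }
  for (i in seq_len(half)) {
    r <- runif(d)
    I <- 1 + (runif(d) >= 0.5)
    cand <- numeric(d)
    for (j in seq_len(d)) {
      cand[j] <- agents[i, j] + r[j] * (best[j] - I[j] * agents[i, j])
    }
    accept(i, oracleClip(cand, lower, upper))
  }
  for (i in seq.int(half + 1, P)) {
    rg <- runif(d)
    ig <- numeric(d)
    for (j in seq_len(d)) ig[j] <- lower[j] + rg[j] * (upper[j] - lower[j])
    fg <- fitness(ig)
    r <- runif(d)
    I <- 1 + (runif(d) >= 0.5)
    cand <- numeric(d)
    for (j in seq_len(d)) {
      cand[j] <- if (fg < fit[i]) {
        agents[i, j] + r[j] * (ig[j] - I[j] * agents[i, j])
      } else {
        agents[i, j] + r[j] * (agents[i, j] - ig[j])
      }
    }
    accept(i, oracleClip(cand, lower, upper))
  }
  for (i in seq_len(P)) {
    r <- runif(d)
    cand <- numeric(d)
    for (j in seq_len(d)) {
      lbl <- lower[j] / t
      ubl <- upper[j] / t
      cand[j] <- agents[i, j] + (1 - 2 * r[j]) * (lbl + r[j] * (ubl - lbl))
    }
    accept(i, oracleClip(cand, lower, upper))
  }
  list(agents = agents, fit = fit, best = best, bestF = bestF)
}

# direct-summation depthwise convolution (valid padding, stride 1)
oracleDepthwise <- function(x, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  oh <- H - kh + 1; ow <- W - kw + 1
  g <- array(0, c(oh, ow, C))
  for (m in seq_len(C)) {
    for (i in seq_len(oh)) {
      for (j in seq_len(ow)) {
        acc <- 0
        for (w in seq_len(kh)) {
          for (h in seq_len(kw)) {
            acc <- acc + k[w, h, m] * x[i + w - 1, j + h - 1, m]
          }
        }
        g[i, j, m] <- acc
      }
    }
  }
  g
}

# scalar pool -> 1D conv -> sigmoid -> rescale transcription of ECA
oracleECA <- function(x, w) {
  C <- dim(x)[3]
  k <- length(w)
  pad <- (k - 1) / 2
  favg <- numeric(C)
  for (c in seq_len(C)) favg[c] <- mean(x[, , c])
  fp <- c(rep(0, pad), favg, rep(0, pad))
  out <- array(0, dim(x))
  for (c in seq_len(C)) {
    s <- 0
    for (j in seq_len(k)) s <- s + w[j] * fp[c + j - 1]
    mc <- 1 / (1 + exp(-s))
    out[, , c] <- x[, , c] * mc
  }
  out
}

# nearest-mean-colour baseline used to calibrate synthetic difficulty
centroidAccuracy <- function(trainSet, testSet) {
  feat <- function(set) {
    t(vapply(imageData(set), function(im) {
      c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3]))
    }, numeric(3)))
  }
  ftr <- feat(trainSet)
  fte <- feat(testSet)
  k <- length(classNames(trainSet))
  centroids <- t(vapply(seq_len(k), function(c) {
    colMeans(ftr[imageLabels(trainSet) == c, , drop = FALSE])
  }, numeric(3)))
  pred <- apply(fte, 1, function(v) {
    which.min(colSums((t(centroids) - v)^2))
  })
  100 * mean(pred == imageLabels(testSet))
}

# small random labelled scores for AUC checks
randomScoreSet <- function(n, k) {
  y <- sample.int(k, n, replace = TRUE)
  s <- matrix(rexp(n * k), n, k)
  s <- s / rowSums(s)
  list(y = y, scores = s)
}
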