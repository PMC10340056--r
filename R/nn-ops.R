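#' @include utils.R
NULL

# Feature maps are stored as H x W x C numeric arrays (row, column,
# channel); batched tensors elsewhere in the package add a trailing
# sample dimension.

#' Depthwise convolution
#'
#' Convolves each channel with its own kernel (no cross-channel mixing):
#' `G[i, j, m] = sum_{w, h} K[w, h, m] * X[i + w, j + h, m]` with valid
#' padding and stride 1.
#'
#' @param x `H x W x C` feature map.
#' @param k `kh x kw x C` per-channel kernel stack.
#' @return the `(H - kh + 1) x (W - kw + 1) x C` output map.
#' @export
#' @examples
#' x <- array(1, c(4, 4, 2))
#' k <- array(1, c(1, 1, 2))
#' identical(depthwiseConv(x, k), x)
depthwiseConv <- function(x, k) {
  stopifnot(length(dim(x)) == 3L, length(dim(k)) == 3L)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  if (dim(k)[3] != C) stop("kernel channel count must match the input")
  if (kh > H || kw > W) stop("kernel larger than the input")
  oh <- H - kh + 1L; ow <- W - kw + 1L
  g <- array(0, c(oh, ow, C))
  for (dh in seq_len(kh)) {
    for (dw in seq_len(kw)) {
      slice <- x[dh:(dh + oh - 1L), dw:(dw + ow - 1L), , drop = FALSE]
      g <- g + sweep(slice, 3L, k[dh, dw, ], "*")
    }
  }
  g
}

#' Computation cost of depthwise-separable vs standard convolution
#'
#' For a `Df x Df` feature map, `Dk x Dk` kernels, `M` input and `N`
#' output channels, the separable unit (depthwise + 1x1 pointwise) costs
#' `Q1 = Df^2 Dk^2 M + Df^2 M N` multiply-accumulates against
#' `Q2 = Df^2 Dk^2 M N` for the standard convolution, giving
#' `Q1 / Q2 = 1/N + 1/Dk^2`; with 3x3 kernels this tends to 1/9 as `N`
#' grows.
#'
#' @param Df feature-map side length.
#' @param Dk kernel side length.
#' @param M input channels.
#' @param N output channels.
#' @return list with `Q1`, `Q2` and `ratio`.
#' @export
#' @examples
#' separableConvCost(16, 3, 8, 64)$ratio # 1/64 + 1/9
separableConvCost <- function(Df, Dk, M, N) {
  stopifnot(Df >= 1, Dk >= 1, M >= 1, N >= 1)
  q1 <- Df^2 * Dk^2 * M + Df^2 * M * N
  q2 <- Df^2 * Dk^2 * M * N
  list(Q1 = q1, Q2 = q2, ratio = q1 / q2)
}

# channel permutation used by the shuffle: reshape (g, C/g), transpose,
# flatten (row-major semantics)
shufflePermutation <- function(C, g) {
  if (C %% g != 0L) stop("channel count must be divisible by the groups")
  as.vector(t(matrix(seq_len(C), ncol = g)))
}

#' Channel shuffle
#'
#' Deterministically permutes channels so information can flow between
#' grouped convolutions: channels are reshaped to `(g, C/g)`, transposed
#' and flattened. Spatial content is untouched and the operation is a
#' bijection on channels; shuffling with `g` then with `C/g` is the
#' identity.
#'
#' @param x `H x W x C` feature map.
#' @param g number of groups (`C` must be divisible by `g`).
#' @return the shuffled feature map.
#' @export
#' @examples
#' x <- array(seq_len(4), c(1, 1, 4))
#' as.vector(channelShuffle(x, 2)) # 1 3 2 4
channelShuffle <- function(x, g) {
  stopifnot(length(dim(x)) == 3L)
  perm <- shufflePermutation(dim(x)[3], g)
  x[, , perm, drop = FALSE]
}

# 1D convolution with zero same-padding (odd kernel), used by ECA
conv1dSame <- function(v, w) {
  k <- length(w)
  if (k %% 2L == 0L) stop("1D kernel length must be odd")
  pad <- (k - 1L) %/% 2L
  vp <- c(rep(0, pad), v, rep(0, pad))
  n <- length(v)
  out <- numeric(n)
  for (j in seq_len(k)) out <- out + w[j] * vp[j:(j + n - 1L)]
  out
}

#' Efficient channel attention (ECA)
#'
#' Global average pooling produces one descriptor per channel; a short 1D
#' convolution across channels followed by a sigmoid yields attention
#' weights in `(0, 1)`, which rescale each channel of the input:
#' `F'[c, , ] = F[c, , ] * Mc[c]`. With all-zero convolution weights the
#' attention is exactly `sigmoid(0) = 0.5` everywhere.
#'
#' @param x `H x W x C` feature map.
#' @param weights numeric 1D-convolution kernel of odd length `k <= C`.
#' @return the reweighted feature map, with the attention vector attached
#'   as attribute `"attention"`.
#' @export
#' @examples
#' x <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
#' out <- ecaModule(x, c(0, 0, 0))
#' all.equal(out, 0.5 * x, check.attributes = FALSE)
ecaModule <- function(x, weights) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[3]
  if (length(weights) %% 2L == 0L) stop("ECA kernel length must be odd")
  if (length(weights) > C) stop("ECA kernel longer than the channel axis")
  favg <- apply(x, 3L, mean)
  mc <- stableSigmoid(conv1dSame(favg, weights))
  out <- sweep(x, 3L, mc, "*")
  attr(out, "attention") <- mc
  out
}
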