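#' Derive a stream seed from a global seed and a label
#'
#' One global seed determines every RNG stream in the package (optimizers,
#' data generation, splitting, training). Streams are separated by hashing
#' a short label into the seed with 31-bit modular arithmetic, so all
#' derived seeds stay below 2^31.
#'
#' @param seed integer global seed.
#' @param label character stream label, e.g. `"split"` or `"ber"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1, "split")
deriveSeed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  s <- ((abs(as.numeric(seed)) %% m) * 48271 + h + 1) %% m
  as.integer(s %/% 1 + 1)
}

# clip a numeric vector to box constraints
clipToBounds <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# evaluate a fitness function defensively: non-finite values become +Inf
# with a warning, per the optimizer error contract
safeFitness <- function(fitness, x) {
  v <- fitness(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    warning("fitness returned a non-finite value; recording +Inf",
            call. = FALSE)
    return(Inf)
  }
  as.numeric(v)
}

checkBounds <- function(lower, upper) {
  if (length(lower) == 0L) stop("search space is empty")
  if (length(lower) != length(upper)) {
    stop("lower and upper bounds differ in length")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  invisible(TRUE)
}

stableSigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}
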