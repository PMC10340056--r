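#' @include AllClasses.R
NULL

# round half away from zero (base round() goes to even)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

decodeOne <- function(p, u) {
  u <- min(max(u, 0), 1)
  if (p@kind == "categorical") {
    k <- length(p@choices)
    idx <- min(k, floor(u * k) + 1L)
    return(p@choices[[idx]])
  }
  v <- if (p@scale == "log") {
    10^(log10(p@lower) + u * (log10(p@upper) - log10(p@lower)))
  } else {
    p@lower + u * (p@upper - p@lower)
  }
  if (p@kind == "integer") v <- roundHalfAway(v)
  v
}

encodeOne <- function(p, value) {
  if (p@kind == "categorical") {
    idx <- which(vapply(p@choices, identical, logical(1),
                        y = value))
    if (!length(idx)) {
      # numeric categorical values may arrive coerced; match by value
      idx <- which(vapply(p@choices, function(c) {
        isTRUE(all.equal(as.numeric(c), as.numeric(value)))
      }, logical(1)))
    }
    if (!length(idx)) stop(sprintf("value not among choices of '%s'",
                                   p@name))
    k <- length(p@choices)
    return((idx[1L] - 0.5) / k) # bin midpoint
  }
  if (p@upper == p@lower) return(0.5)
  if (p@scale == "log") {
    (log10(value) - log10(p@lower)) / (log10(p@upper) - log10(p@lower))
  } else {
    (value - p@lower) / (p@upper - p@lower)
  }
}

#' Decode a unit-box vector into a hyperparameter record
#'
#' Optimizers search `[0,1]^d`; this maps each coordinate into its
#' physical range: linear or log interpolation for continuous dimensions,
#' rounding half away from zero for integers, and equal-width bins for
#' categorical choices. Out-of-box coordinates are clipped before
#' decoding.
#'
#' @param x numeric vector in (or clipped to) `[0,1]^d`.
#' @param space a [SearchSpace-class].
#' @return named list of decoded hyperparameter values.
#' @export
#' @examples
#' sp <- searchSpace(hyperParam("lr", "continuous", 1e-4, 1e-1,
#'                              scale = "log"))
#' decodeVector(0.5, sp) # geometric midpoint
decodeVector <- function(x, space) {
  stopifnot(is(space, "SearchSpace"))
  if (length(x) != length(space)) {
    stop("vector length does not match search-space dimension")
  }
  out <- lapply(seq_along(space@params), function(j) {
    decodeOne(space@params[[j]], x[j])
  })
  names(out) <- names(space)
  out
}

#' Encode a hyperparameter record into the unit box
#'
#' Inverse of [decodeVector()] up to the rounding rules: for integer and
#' categorical dimensions `decodeVector(encodePoint(p, space), space)`
#' recovers `p` exactly.
#'
#' @param record named list of hyperparameter values.
#' @param space a [SearchSpace-class].
#' @return numeric vector in `[0,1]^d`.
#' @export
encodePoint <- function(record, space) {
  stopifnot(is(space, "SearchSpace"))
  vapply(space@params, function(p) {
    if (is.null(record[[p@name]])) {
      stop(sprintf("record is missing '%s'", p@name))
    }
    encodeOne(p, record[[p@name]])
  }, numeric(1))
}
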