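#' @include AllClasses.R utils.R
NULL

# The BER operators consume the current R RNG stream in a documented
# order so that an independent scalar transcription fed the same stream
# reproduces every move bit-for-bit:
#   exploration:        r1 (d draws), then r2 (d draws)
#   toward-leader:      r3 (d draws), then r2 (d draws)
#   around-leader:      z (1), h (1, on [0,2]), x (1, on (0,180), resampled
#                       while |1 - cos x| <= 1e-12)
#   mutation:           z (d), h (d), x (d, with the same resampling)
# Within an iteration, exploration agents move first (in index order),
# then exploitation agents, each preceded by one uniform coin that picks
# toward-leader (< 0.5) or around-leader (>= 0.5).

# draw n angles uniformly on (0, 180) degrees, resampling entries whose
# cosine is within 1e-12 of 1 (guards the 1 - cos(x) denominator)
drawAngle <- function(n) {
  x <- runif(n, 0, 180)
  repeat {
    bad <- abs(1 - cos(x * pi / 180)) <= 1e-12
    if (!any(bad)) return(x)
    x[bad] <- runif(sum(bad), 0, 180)
  }
}

#' Al-Biruni Earth Radius coefficient
#'
#' The scalar step-size coefficient `r = h cos(x) / (1 - cos(x))` used by
#' the around-leader and mutation moves; `h` is a random magnitude in
#' `[0, 2]` and `x` an angle in degrees.
#'
#' @param h numeric in `[0, 2]`.
#' @param xDeg angle in degrees, `0 < xDeg <= 180`.
#' @return a finite numeric scalar.
#' @export
#' @examples
#' berRadius(2, 180) # -1
berRadius <- function(h, xDeg) {
  if (any(xDeg <= 0) || any(xDeg > 180)) {
    stop("angle must satisfy 0 < x <= 180 degrees")
  }
  cx <- cos(xDeg * pi / 180)
  if (any(abs(1 - cx) <= 1e-12)) {
    stop("angle too close to 0: 1 - cos(x) underflows")
  }
  h * cx / (1 - cx)
}

#' BER exploration move
#'
#' Proposes `S + D * (2 r2 - 1)` with diameter `D = r1 * (S - 1)`
#' (elementwise), `r1, r2 ~ U(0,1)^d` drawn from the current RNG stream
#' (`r1` first). The candidate is clipped to the box; its fitness is not
#' evaluated here.
#'
#' @param values current position (numeric vector).
#' @param lower,upper box constraints.
#' @return the candidate position.
#' @export
berExplorationStep <- function(values, lower, upper) {
  d <- length(values)
  r1 <- runif(d)
  r2 <- runif(d)
  D <- r1 * (values - 1)
  clipToBounds(values + D * (2 * r2 - 1), lower, upper)
}

#' BER exploitation move toward the leader
#'
#' Proposes `r2 * (S + D)` with `D = r3 * (L - S)` elementwise;
#' `r3` is drawn before `r2`, both `U(0,1)^d`.
#'
#' @param values current position.
#' @param leader current best position `L`.
#' @param lower,upper box constraints.
#' @return the candidate position, clipped to the box.
#' @export
berExploitTowardLeader <- function(values, leader, lower, upper) {
  d <- length(values)
  r3 <- runif(d)
  r2 <- runif(d)
  D <- r3 * (leader - values)
  clipToBounds(r2 * (values + D), lower, upper)
}

#' BER exploitation move around the leader
#'
#' Proposes `r * (S* + k)` with `k = z + 2 t^2 / N^2` (scalar, growing
#' over the run) and `r = berRadius(h, x)`. Draw order: `z`, `h`, `x`.
#'
#' @param best leader position `S*`.
#' @param t current iteration (1-based).
#' @param N iteration budget.
#' @param lower,upper box constraints.
#' @return the candidate position, clipped to the box.
#' @export
berExploitAroundLeader <- function(best, t, N, lower, upper) {
  if (N == 0) stop("iteration budget N must be positive")
  z <- runif(1)
  h <- runif(1, 0, 2)
  x <- drawAngle(1)
  r <- berRadius(h, x)
  k <- z + 2 * t^2 / N^2
  clipToBounds(r * (best + k), lower, upper)
}

#' BER mutation move
#'
#' Replaces a position with `k * z^2 - h cos(x)/(1 - cos(x))` computed
#' independently per dimension with fresh `z`, `h`, `x` (drawn as three
#' d-length vectors, in that order); `k = z + 2 t^2 / N^2` reuses the
#' dimension's own `z`. The result does not depend on any current agent.
#'
#' @param t current iteration.
#' @param N iteration budget.
#' @param lower,upper box constraints (define the dimension).
#' @return a new position, clipped to the box.
#' @export
berMutationStep <- function(t, N, lower, upper) {
  if (N == 0) stop("iteration budget N must be positive")
  d <- length(lower)
  z <- runif(d)
  h <- runif(d, 0, 2)
  x <- drawAngle(d)
  r <- berRadius(h, x)
  k <- z + 2 * t^2 / N^2
  clipToBounds(k * z^2 - r, lower, upper)
}

# initialize a BER state: agents uniform in the box, all evaluated
berInit <- function(fitness, lower, upper, populationSize) {
  d <- length(lower)
  agents <- matrix(runif(populationSize * d), nrow = populationSize)
  agents <- sweep(sweep(agents, 2, upper - lower, "*"), 2, lower, "+")
  fit <- apply(agents, 1, function(x) safeFitness(fitness, x))
  ibest <- which.min(fit)
  list(
    agents = agents, fitness = fit,
    best = list(values = agents[ibest, ], fitness = fit[ibest]),
    t = 0L, stagnation = 0L
  )
}

#' Run one BER iteration
#'
#' Exploration agents move by [berExplorationStep()]; exploitation agents
#' flip a fair coin between [berExploitTowardLeader()] and
#' [berExploitAroundLeader()]. Every candidate is accepted greedily
#' (kept only if strictly better) and the best-ever record (elitism) is
#' refreshed after each acceptance. If the best fitness has not improved
#' by more than `stagnationTol` for `stagnationWindow` consecutive
#' iterations, the exploration subgroup is replaced via
#' [berMutationStep()] and the counter resets.
#'
#' Uses the current RNG stream (see the package vignette for the
#' documented draw order); [berOptimize()] seeds it once per run.
#'
#' @param state list with `agents` (matrix), `fitness`, `best`, `t`,
#'   `stagnation`, as produced by [berOptimize()] internals.
#' @param fitness objective function mapping a vector to a scalar
#'   (minimized); non-finite returns are recorded as `+Inf` with a
#'   warning.
#' @param config a [BERConfig-class].
#' @param lower,upper box constraints.
#' @return the updated state, with `mutationFired` and `meanFitness`
#'   fields describing the completed iteration.
#' @export
berIterate <- function(state, fitness, config, lower, upper) {
  P <- nrow(state$agents)
  nExplore <- max(1L, min(P - 1L,
                          as.integer(round(config@explorationFraction * P))))
  t <- state$t + 1L
  N <- config@iterations
  bestBefore <- state$best$fitness

  acceptCandidate <- function(i, cand) {
    f <- safeFitness(fitness, cand)
    if (f < state$fitness[i]) {
      state$agents[i, ] <<- cand
      state$fitness[i] <<- f
      if (f < state$best$fitness) {
        state$best <<- list(values = cand, fitness = f)
      }
    }
  }

  for (i in seq_len(nExplore)) {
    cand <- berExplorationStep(state$agents[i, ], lower, upper)
    acceptCandidate(i, cand)
  }
  for (i in seq.int(nExplore + 1L, P)) {
    if (runif(1) < 0.5) {
      cand <- berExploitTowardLeader(state$agents[i, ], state$best$values,
                                     lower, upper)
    } else {
      cand <- berExploitAroundLeader(state$best$values, t, N, lower, upper)
    }
    acceptCandidate(i, cand)
  }

  mutationFired <- FALSE
  improvement <- bestBefore - state$best$fitness
  if (is.nan(improvement)) improvement <- 0 # both Inf: no progress
  if (improvement < config@stagnationTol) {
    state$stagnation <- state$stagnation + 1L
  } else {
    state$stagnation <- 0L
  }
  if (state$stagnation >= config@stagnationWindow) {
    for (i in seq_len(nExplore)) {
      newv <- berMutationStep(t, N, lower, upper)
      f <- safeFitness(fitness, newv)
      state$agents[i, ] <- newv
      state$fitness[i] <- f
      if (f < state$best$fitness) {
        state$best <- list(values = newv, fitness = f)
      }
    }
    state$stagnation <- 0L
    mutationFired <- TRUE
  }

  state$t <- t
  state$mutationFired <- mutationFired
  state$meanFitness <- mean(state$fitness[is.finite(state$fitness)])
  state
}

#' Al-Biruni Earth Radius optimization
#'
#' Bound-constrained minimization with exploration/exploitation
#' subgroups, elitism, and stagnation-triggered mutation. The reported
#' best-fitness history is non-increasing for every objective and seed,
#' and identical seeds give bit-identical runs.
#'
#' @param fitness objective function (minimized).
#' @param lower,upper numeric vectors defining the box.
#' @param config a [BERConfig-class].
#' @param logFile optional path; when given, the run log (iteration,
#'   best_fitness, mean_fitness, mutation_fired) is written as CSV.
#' @return list with `best` (list of `values`, `fitness`), `history` (a
#'   data frame with one row per iteration) and `initialFitness`, the
#'   best fitness after initialization (iteration 0).
#' @export
#' @examples
#' res <- berOptimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'                    berConfig(populationSize = 10, iterations = 25,
#'                              seed = 7))
#' res$best$fitness
berOptimize <- function(fitness, lower, upper, config = berConfig(),
                        logFile = NULL) {
  checkBounds(lower, upper)
  validObject(config)
  set.seed(config@seed)
  state <- berInit(fitness, lower, upper, config@populationSize)
  initialFitness <- state$best$fitness
  n <- config@iterations
  history <- data.frame(
    iteration = seq_len(n), best_fitness = NA_real_,
    mean_fitness = NA_real_, mutation_fired = 0L
  )
  for (it in seq_len(n)) {
    state <- berIterate(state, fitness, config, lower, upper)
    history$best_fitness[it] <- state$best$fitness
    history$mean_fitness[it] <- state$meanFitness
    history$mutation_fired[it] <- as.integer(state$mutationFired)
  }
  if (!is.null(logFile)) writeRunLog(history, logFile)
  list(best = state$best, history = history,
       initialFitness = initialFitness)
}
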