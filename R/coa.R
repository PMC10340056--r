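#' @include AllClasses.R utils.R
NULL

# COA draw order (one iteration, replayable by a scalar transcription):
#   phase 1, climbers (i = 1..floor(P/2)):   r (d), I (d)
#   phase 1, ground (i = floor(P/2)+1..P):   rG (d) for the fallen iguana,
#       then r (d) and I (d); r and I are drawn before the Eq-17 branch is
#       taken so the stream does not depend on the branch
#   phase 2 (all agents):                    r (d), reused inside the move
# I entries are 1 + (u >= 0.5) with u ~ U(0,1).

drawI <- function(d) 1 + (runif(d) >= 0.5)

#' COA tree-climbing (iguana attack) move
#'
#' Proposes `x + r * (Iguana - I * x)` per dimension, with fresh
#' `r ~ U(0,1)` and `I` in `{1, 2}` per dimension (`r` vector drawn first).
#'
#' @param values current position.
#' @param iguana position of the best agent.
#' @param lower,upper box constraints.
#' @return the candidate position, clipped to the box.
#' @export
coaClimbStep <- function(values, iguana, lower, upper) {
  d <- length(values)
  r <- runif(d)
  I <- drawI(d)
  clipToBounds(values + r * (iguana - I * values), lower, upper)
}

#' Random ground position for the fallen iguana
#'
#' `lb + r * (ub - lb)` with fresh `r` per dimension.
#'
#' @param lower,upper box constraints.
#' @return a position inside the box.
#' @export
coaGroundIguana <- function(lower, upper) {
  lower + runif(length(lower)) * (upper - lower)
}

#' COA ground move relative to the fallen iguana
#'
#' If the ground iguana is fitter than the agent, the agent moves toward
#' it (`x + r * (IguanaG - I * x)`), otherwise away from it
#' (`x + r * (x - IguanaG)`). `r` and `I` are drawn before the branch.
#'
#' @param values current position.
#' @param iguanaG ground-iguana position.
#' @param fIguanaG,fAgent fitness of the ground iguana and of the agent.
#' @param lower,upper box constraints.
#' @return the candidate position, clipped to the box.
#' @export
coaGroundStep <- function(values, iguanaG, fIguanaG, fAgent,
                          lower, upper) {
  d <- length(values)
  r <- runif(d)
  I <- drawI(d)
  cand <- if (fIguanaG < fAgent) {
    values + r * (iguanaG - I * values)
  } else {
    values + r * (values - iguanaG)
  }
  clipToBounds(cand, lower, upper)
}

#' Greedy acceptance
#'
#' Keeps the candidate only when its fitness is strictly smaller.
#'
#' @param current,candidate lists with `values` and `fitness`.
#' @return whichever of the two solutions has the strictly better
#'   (smaller) fitness; ties keep `current`.
#' @export
#' @examples
#' greedyAccept(list(values = 1, fitness = 5),
#'              list(values = 2, fitness = 3))$fitness # 3
greedyAccept <- function(current, candidate) {
  if (candidate$fitness < current$fitness) candidate else current
}

#' Shrinking local bounds
#'
#' `lb/t, ub/t`: at `t = 1` the local box equals the global box; the
#' escape neighbourhood then contracts as `1/t`.
#'
#' @param lower,upper global box.
#' @param t iteration counter, `t >= 1`.
#' @return list with `lower` and `upper` local bounds.
#' @export
coaLocalBounds <- function(lower, upper, t) {
  if (t < 1) stop("t must be >= 1")
  list(lower = lower / t, upper = upper / t)
}

#' COA predator-escape move
#'
#' Proposes `x + (1 - 2r) * (lb_local + r * (ub_local - lb_local))` with
#' one fresh `r` per dimension (used in both factors). The candidate is
#' clipped to the global box; the local bounds only shape the proposal.
#'
#' @param values current position.
#' @param boundsLocal list with local `lower`/`upper`
#'   (from [coaLocalBounds()]).
#' @param lower,upper global box constraints.
#' @return the candidate position.
#' @export
coaEscapeStep <- function(values, boundsLocal, lower, upper) {
  d <- length(values)
  r <- runif(d)
  step <- (1 - 2 * r) * (boundsLocal$lower +
                           r * (boundsLocal$upper - boundsLocal$lower))
  clipToBounds(values + step, lower, upper)
}

coaInit <- function(fitness, lower, upper, populationSize) {
  d <- length(lower)
  agents <- matrix(runif(populationSize * d), nrow = populationSize)
  agents <- sweep(sweep(agents, 2, upper - lower, "*"), 2, lower, "+")
  fit <- apply(agents, 1, function(x) safeFitness(fitness, x))
  ibest <- which.min(fit)
  list(
    agents = agents, fitness = fit,
    best = list(values = agents[ibest, ], fitness = fit[ibest]),
    t = 0L
  )
}

#' Run one COA iteration
#'
#' Phase 1: the first half of the population climbs toward the best agent
#' ([coaClimbStep()]); each agent of the second half reacts to a freshly
#' drawn ground iguana ([coaGroundIguana()], [coaGroundStep()]). Phase 2:
#' every agent makes a predator-escape move inside `1/t`-shrinking local
#' bounds. All moves are accepted greedily and the best-ever record is
#' refreshed after every acceptance. The ground iguana is a transient
#' reference point and never enters the population.
#'
#' @param state list with `agents`, `fitness`, `best`, `t`.
#' @param fitness objective function (minimized).
#' @param config a [COAConfig-class].
#' @param lower,upper box constraints.
#' @return the updated state (with `meanFitness`).
#' @export
coaIterate <- function(state, fitness, config, lower, upper) {
  P <- nrow(state$agents)
  half <- floor(P / 2)
  t <- state$t + 1L

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

  for (i in seq_len(half)) {
    cand <- coaClimbStep(state$agents[i, ], state$best$values,
                         lower, upper)
    acceptCandidate(i, cand)
  }
  for (i in seq.int(half + 1L, P)) {
    ig <- coaGroundIguana(lower, upper)
    fg <- safeFitness(fitness, ig)
    cand <- coaGroundStep(state$agents[i, ], ig, fg, state$fitness[i],
                          lower, upper)
    acceptCandidate(i, cand)
  }

  bl <- coaLocalBounds(lower, upper, t)
  for (i in seq_len(P)) {
    cand <- coaEscapeStep(state$agents[i, ], bl, lower, upper)
    acceptCandidate(i, cand)
  }

  state$t <- t
  state$meanFitness <- mean(state$fitness[is.finite(state$fitness)])
  state
}

#' Coati Optimization Algorithm
#'
#' Bound-constrained minimization alternating an iguana-attack
#' exploration phase with a predator-escape exploitation phase under
#' `1/t`-shrinking local bounds. Greedy acceptance makes every agent's
#' stored fitness non-increasing, so the best-fitness history never
#' worsens; identical seeds give bit-identical runs.
#'
#' @param fitness objective function (minimized).
#' @param lower,upper numeric vectors defining the box.
#' @param config a [COAConfig-class].
#' @param logFile optional CSV run-log path (same schema as
#'   [berOptimize()]; `mutation_fired` is always 0).
#' @return list with `best`, per-iteration `history`, and
#'   `initialFitness` (the best fitness after initialization).
#' @export
#' @examples
#' res <- coaOptimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'                    coaConfig(populationSize = 10, iterations = 25,
#'                              seed = 7))
#' res$best$fitness
coaOptimize <- function(fitness, lower, upper, config = coaConfig(),
                        logFile = NULL) {
  checkBounds(lower, upper)
  validObject(config)
  set.seed(config@seed)
  state <- coaInit(fitness, lower, upper, config@populationSize)
  initialFitness <- state$best$fitness
  n <- config@iterations
  history <- data.frame(
    iteration = seq_len(n), best_fitness = NA_real_,
    mean_fitness = NA_real_, mutation_fired = 0L
  )
  for (it in seq_len(n)) {
    state <- coaIterate(state, fitness, config, lower, upper)
    history$best_fitness[it] <- state$best$fitness
    history$mean_fitness[it] <- state$meanFitness
  }
  if (!is.null(logFile)) writeRunLog(history, logFile)
  list(best = state$best, history = history,
       initialFitness = initialFitness)
}

#' Write an optimizer run log
#'
#' CSV with columns `iteration, best_fitness, mean_fitness,
#' mutation_fired`, shared by both optimizers.
#'
#' @param history data frame as returned in `$history`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRunLog <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
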