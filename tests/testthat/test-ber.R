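test_that("berRadius matches closed-form values and guards the domain", {
  expect_equal(berRadius(1.3, 90), 0, tolerance = 1e-12)
  expect_equal(berRadius(2, 180), -1)
  expect_equal(berRadius(0.7, 60), 0.7 * cos(pi / 3) / (1 - cos(pi / 3)))
  expect_error(berRadius(1, 0), "0 < x")
  expect_error(berRadius(1, 1e-9), "underflow")
})

test_that("exploration leaves an all-ones agent in place (zero diameter)", {
  set.seed(1)
  s <- rep(1, 4)
  expect_equal(berExplorationStep(s, rep(-5, 4), rep(5, 4)), s)
})

test_that("single moves agree with per-equation scalar oracles", {
  lower <- rep(-5, 3); upper <- rep(5, 3)
  s <- c(0.4, -1.2, 2.5)
  leader <- c(0.1, 0.2, -0.3)

  set.seed(11)
  got <- berExplorationStep(s, lower, upper)
  set.seed(11)
  r1 <- runif(3); r2 <- runif(3)
  want <- vapply(1:3, function(j) {
    s[j] + (r1[j] * (s[j] - 1)) * (2 * r2[j] - 1)
  }, numeric(1))
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)

  set.seed(12)
  got <- berExploitTowardLeader(s, leader, lower, upper)
  set.seed(12)
  r3 <- runif(3); r2 <- runif(3)
  want <- vapply(1:3, function(j) {
    r2[j] * (s[j] + r3[j] * (leader[j] - s[j]))
  }, numeric(1))
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)

  set.seed(13)
  got <- berExploitAroundLeader(leader, t = 4, N = 10, lower, upper)
  set.seed(13)
  z <- runif(1); h <- runif(1, 0, 2); x <- oracleDrawAngle(1)
  k <- z + 2 * 4^2 / 10^2
  want <- oracleRadius(h, x) * (leader + k)
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)

  set.seed(14)
  got <- berMutationStep(t = 2, N = 10, lower, upper)
  set.seed(14)
  z <- runif(3); h <- runif(3, 0, 2); x <- oracleDrawAngle(3)
  want <- vapply(1:3, function(j) {
    (z[j] + 2 * 2^2 / 10^2) * z[j]^2 - oracleRadius(h[j], x[j])
  }, numeric(1))
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)
})

test_that("a full 3-agent iteration equals the scalar transcription", {
  lower <- rep(-4, 2); upper <- rep(4, 2)
  sphere <- function(x) sum((x - 0.5)^2)
  cfg <- berConfig(populationSize = 3, iterations = 10,
                   explorationFraction = 0.5, seed = 1)
  agents <- matrix(c(1.5, -2, 0.3, 2.2, -1.1, 0.8), nrow = 3,
                   byrow = TRUE)
  fit <- apply(agents, 1, sphere)
  ib <- which.min(fit)
  state <- list(agents = agents, fitness = fit,
                best = list(values = agents[ib, ], fitness = fit[ib]),
                t = 0L, stagnation = 0L)
  for (rep in 1:4) { # several iterations so both exploit branches occur
    seed <- 100 + rep
    set.seed(seed)
    got <- berIterate(state, sphere, cfg, lower, upper)
    set.seed(seed)
    want <- oracleBERIterate(state$agents, state$fitness,
                             state$best$values, state$best$fitness,
                             t = state$t + 1, N = 10, nExplore = 2,
                             stagnation = state$stagnation, window = 3,
                             tol = 1e-9, lower, upper, sphere)
    expect_equal(got$agents, want$agents, tolerance = 1e-12)
    expect_equal(got$fitness, want$fit, tolerance = 1e-12)
    expect_equal(got$best$values, want$best, tolerance = 1e-12)
    expect_equal(got$best$fitness, want$bestF, tolerance = 1e-12)
    expect_equal(got$stagnation, as.integer(want$stagnation))
    state <- got
  }
})

test_that("elitism: best-fitness history is non-increasing and within bounds", {
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  for (seed in 1:5) {
    res <- berOptimize(rastrigin, rep(-5.12, 4), rep(5.12, 4),
                       berConfig(populationSize = 8, iterations = 30,
                                 seed = seed))
    expect_false(is.unsorted(-res$history$best_fitness))
    expect_true(all(res$best$values >= -5.12 & res$best$values <= 5.12))
    expect_lte(res$best$fitness, res$initialFitness)
  }
})

test_that("identical seeds give bit-identical histories", {
  f <- function(x) sum(abs(x))
  a <- berOptimize(f, rep(-3, 3), rep(3, 3),
                   berConfig(populationSize = 6, iterations = 15,
                             seed = 42))
  b <- berOptimize(f, rep(-3, 3), rep(3, 3),
                   berConfig(populationSize = 6, iterations = 15,
                             seed = 42))
  expect_identical(a$history, b$history)
  expect_identical(a$best, b$best)
})

test_that("mutation fires exactly when the stagnation window is reached", {
  flat <- function(x) 1
  res <- berOptimize(flat, rep(-1, 3), rep(1, 3),
                     berConfig(populationSize = 6, iterations = 8,
                               stagnationWindow = 3, seed = 5))
  fired <- which(res$history$mutation_fired == 1)
  expect_equal(fired, c(3L, 6L)) # counter resets after each firing
  res4 <- berOptimize(flat, rep(-1, 3), rep(1, 3),
                      berConfig(populationSize = 6, iterations = 8,
                                stagnationWindow = 4, seed = 5))
  expect_equal(which(res4$history$mutation_fired == 1), c(4L, 8L))
})

test_that("non-finite fitness values are recorded as +Inf with a warning", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(
    res <- berOptimize(bad, rep(-1, 2), rep(1, 2),
                       berConfig(populationSize = 4, iterations = 3,
                                 seed = 3)),
    "non-finite"
  )
  expect_true(is.finite(res$best$fitness))
})

test_that("degenerate configurations are rejected", {
  expect_error(berOptimize(function(x) 0, numeric(0), numeric(0),
                           berConfig()), "empty")
  expect_error(berConfig(populationSize = 2, explorationFraction = 0.95),
               "at least one agent")
})
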