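test_that("greedy acceptance keeps the strictly better solution, ties keep current", {
  cur <- list(values = 1, fitness = 5)
  expect_equal(greedyAccept(cur, list(values = 2, fitness = 3))$fitness, 3)
  expect_equal(greedyAccept(list(values = 1, fitness = 3),
                            list(values = 2, fitness = 5))$values, 1)
  tie <- greedyAccept(cur, list(values = 99, fitness = 5))
  expect_equal(tie$values, 1)
})

test_that("local bounds shrink exactly as 1/t", {
  lb <- c(-10, -2); ub <- c(10, 6)
  b1 <- coaLocalBounds(lb, ub, 1)
  expect_equal(b1$lower, lb)
  expect_equal(b1$upper, ub)
  b2 <- coaLocalBounds(lb, ub, 2)
  expect_equal(b2$lower, c(-5, -1))
  expect_equal(b2$upper, c(5, 3))
  for (t in 2:6) {
    expect_true(all(coaLocalBounds(lb, ub, t)$upper <
                      coaLocalBounds(lb, ub, t - 1)$upper))
  }
  expect_error(coaLocalBounds(lb, ub, 0), ">= 1")
})

test_that("ground iguana lands inside the box, on the bound when degenerate", {
  set.seed(3)
  lb <- c(-2, 4, 7); ub <- c(3, 4, 9) # second dimension degenerate
  for (i in 1:20) {
    p <- coaGroundIguana(lb, ub)
    expect_true(all(p >= lb & p <= ub))
    expect_equal(p[2], 4)
  }
})

test_that("single moves agree with per-equation scalar oracles", {
  lower <- rep(-5, 3); upper <- rep(5, 3)
  x <- c(1.2, -0.7, 3.1)
  ig <- c(0.3, 0.4, -0.2)

  set.seed(21)
  got <- coaClimbStep(x, ig, lower, upper)
  set.seed(21)
  r <- runif(3); I <- 1 + (runif(3) >= 0.5)
  want <- vapply(1:3, function(j) x[j] + r[j] * (ig[j] - I[j] * x[j]),
                 numeric(1))
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)

  for (branch in c(TRUE, FALSE)) { # iguana fitter / agent fitter
    set.seed(22)
    got <- coaGroundStep(x, ig, fIguanaG = if (branch) 0 else 9,
                         fAgent = 5, lower, upper)
    set.seed(22)
    r <- runif(3); I <- 1 + (runif(3) >= 0.5)
    want <- vapply(1:3, function(j) {
      if (branch) x[j] + r[j] * (ig[j] - I[j] * x[j])
      else x[j] + r[j] * (x[j] - ig[j])
    }, numeric(1))
    expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)
  }

  set.seed(23)
  bl <- coaLocalBounds(lower, upper, 3)
  got <- coaEscapeStep(x, bl, lower, upper)
  set.seed(23)
  r <- runif(3)
  want <- vapply(1:3, function(j) {
    x[j] + (1 - 2 * r[j]) * (bl$lower[j] + r[j] * (bl$upper[j] -
                                                     bl$lower[j]))
  }, numeric(1))
  expect_equal(got, oracleClip(want, lower, upper), tolerance = 1e-12)
})

test_that("a full 4-agent iteration equals the scalar transcription", {
  lower <- rep(-4, 2); upper <- rep(4, 2)
  sphere <- function(x) sum((x + 0.3)^2)
  cfg <- coaConfig(populationSize = 4, iterations = 6, seed = 1)
  agents <- matrix(c(1.5, -2, 0.3, 2.2, -1.1, 0.8, 3.0, -0.4),
                   nrow = 4, byrow = TRUE)
  fit <- apply(agents, 1, sphere)
  ib <- which.min(fit)
  state <- list(agents = agents, fitness = fit,
                best = list(values = agents[ib, ], fitness = fit[ib]),
                t = 0L)
  for (rep in 1:3) {
    seed <- 200 + rep
    set.seed(seed)
    got <- coaIterate(state, sphere, cfg, lower, upper)
    set.seed(seed)
    want <- oracleCOAIterate(state$agents, state$fitness,
                             state$best$values, state$best$fitness,
                             t = state$t + 1, lower, upper, sphere)
    expect_equal(got$agents, want$agents, tolerance = 1e-12)
    expect_equal(got$fitness, want$fit, tolerance = 1e-12)
    expect_equal(got$best$values, want$best, tolerance = 1e-12)
    expect_equal(got$best$fitness, want$bestF, tolerance = 1e-12)
    state <- got
  }
})

test_that("greedy acceptance keeps agent fitness non-increasing across a run", {
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  for (seed in 1:5) {
    res <- coaOptimize(rastrigin, rep(-5.12, 4), rep(5.12, 4),
                       coaConfig(populationSize = 8, iterations = 30,
                                 seed = seed))
    expect_false(is.unsorted(-res$history$best_fitness))
    expect_true(all(res$best$values >= -5.12 & res$best$values <= 5.12))
  }
})

test_that("identical seeds give bit-identical histories", {
  f <- function(x) sum(abs(x))
  a <- coaOptimize(f, rep(-3, 3), rep(3, 3),
                   coaConfig(populationSize = 6, iterations = 15,
                             seed = 42))
  b <- coaOptimize(f, rep(-3, 3), rep(3, 3),
                   coaConfig(populationSize = 6, iterations = 15,
                             seed = 42))
  expect_identical(a$history, b$history)
})

test_that("configuration constraints hold", {
  expect_error(coaConfig(populationSize = 1), "non-empty")
  expect_error(coaOptimize(function(x) 0, numeric(0), numeric(0),
                           coaConfig()), "empty")
})
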