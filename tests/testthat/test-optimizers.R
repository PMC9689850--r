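# Benchmark functions, PSO/GA operators and the optimizer driver.

test_that("benchmark functions take their known global minima", {
  expect_equal(benchmark("sphere", rep(0, 10)), 0)
  expect_equal(benchmark("rastrigin", rep(0, 10)), 0)
  expect_equal(benchmark("rosenbrock", rep(1, 10)), 0)
  expect_lt(abs(benchmark("schwefel", rep(420.9687, 10))), 1e-3)
  expect_error(benchmark("nope", 0))
  # positivity away from the optimum
  set.seed(1)
  X <- matrix(runif(50, -5, 5), 5)
  f <- benchmark_function("rastrigin")
  expect_true(all(f(X) > 0))
})

test_that("the asynchronous learning-factor schedule interpolates linearly", {
  cfg <- swarm_config(dim = 2, lower = -1, upper = 1)
  expect_equal(asylncpso_schedule(0, 200, cfg), c(c1 = 2.5, c2 = 0.5))
  expect_equal(asylncpso_schedule(200, 200, cfg), c(c1 = 0.5, c2 = 2.5))
  expect_equal(asylncpso_schedule(100, 200, cfg), c(c1 = 1.5, c2 = 1.5))
  expect_error(asylncpso_schedule(0, 0, cfg), "positive")
})

test_that("a swarm at rest on its global best is a PSO fixed point", {
  cfg <- swarm_config(dim = 3, lower = -5, upper = 5, pop_size = 4)
  f <- benchmark_function("sphere")
  pos <- matrix(1, 4, 3)
  swarm <- list(pos = pos, vel = matrix(0, 4, 3), fit = f(pos),
                pbest_pos = pos, pbest_fit = f(pos),
                gbest_pos = pos[1, ], gbest_fit = f(pos)[1])
  out <- pso_step(swarm, f, cfg)
  expect_equal(out$pos, pos)
  expect_equal(out$vel, matrix(0, 4, 3))
})

test_that("with zero learning factors PSO reduces to inertia drift", {
  cfg <- swarm_config(dim = 2, lower = -100, upper = 100, pop_size = 3,
                      w = 1, c1 = 0, c2 = 0)
  f <- benchmark_function("sphere")
  set.seed(3)
  pos <- matrix(rnorm(6), 3); vel <- matrix(rnorm(6, sd = 0.1), 3)
  swarm <- list(pos = pos, vel = vel, fit = f(pos),
                pbest_pos = pos, pbest_fit = f(pos),
                gbest_pos = pos[1, ], gbest_fit = f(pos)[1])
  out <- pso_step(swarm, f, cfg)
  expect_equal(out$pos, pos + vel)
  expect_equal(out$vel, vel)
})

test_that("velocities stay clamped and positions stay in bounds", {
  cfg <- swarm_config(dim = 4, lower = -2, upper = 2, pop_size = 10,
                      iterations = 30, trials = 1, mode = "PSO", seed = 9)
  f <- benchmark_function("rastrigin")
  set.seed(9)
  state <- new.env(); state$n_evals <- 0; state$n_nonfinite <- 0
  swarm <- sodpselect:::init_swarm(f, cfg, state)
  for (t in 1:30) {
    swarm <- pso_step(swarm, f, cfg, state = state)
    expect_true(all(abs(swarm$vel) <= matrix(cfg$v_max, 10, 4,
                                             byrow = TRUE) + 1e-12))
    expect_true(all(swarm$pos >= -2 & swarm$pos <= 2))
  }
})

test_that("PSO solves the 1-D sphere in nearly all seeded runs", {
  f <- benchmark_function("sphere")
  ok <- vapply(1:20, function(s) {
    cfg <- swarm_config(dim = 1, lower = -100, upper = 100, mode = "PSO",
                        trials = 1, seed = 1000 + s)
    optimize_swarm(f, cfg)$gbest_fitness < 1e-3
  }, logical(1))
  expect_gte(sum(ok), 19)
})

test_that("the genetic pass is inert when its rates are zero", {
  cfg <- swarm_config(dim = 5, lower = -1, upper = 1, pop_size = 8,
                      crossover_rate = 0, mutation_rate = 0)
  f <- benchmark_function("sphere")
  set.seed(21)
  state <- new.env(); state$n_evals <- 0; state$n_nonfinite <- 0
  swarm <- sodpselect:::init_swarm(f, cfg, state)
  before <- swarm
  evals0 <- state$n_evals
  out <- ga_operate(swarm, f, cfg, state)
  expect_equal(out$pos, before$pos)
  expect_equal(out$fit, before$fit)
  expect_equal(state$n_evals, evals0)  # nothing re-evaluated
})

test_that("zero-sigma mutation leaves genes unchanged", {
  cfg <- swarm_config(dim = 5, lower = -1, upper = 1, pop_size = 8,
                      crossover_rate = 0, mutation_rate = 1,
                      mutation_sigma = 0)
  f <- benchmark_function("sphere")
  set.seed(22)
  state <- new.env(); state$n_evals <- 0; state$n_nonfinite <- 0
  swarm <- sodpselect:::init_swarm(f, cfg, state)
  out <- ga_operate(swarm, f, cfg, state)
  expect_equal(out$pos, swarm$pos)
})

test_that("the genetic pass never worsens any individual and keeps the best", {
  cfg <- swarm_config(dim = 6, lower = -5.12, upper = 5.12, pop_size = 12)
  f <- benchmark_function("rastrigin")
  set.seed(31)
  state <- new.env(); state$n_evals <- 0; state$n_nonfinite <- 0
  swarm <- sodpselect:::init_swarm(f, cfg, state)
  for (t in 1:40) {
    prev <- swarm$fit
    best_prev <- min(prev)
    swarm <- ga_operate(swarm, f, cfg, state)
    expect_equal(nrow(swarm$pos), 12)       # population size conserved
    expect_true(all(swarm$fit <= prev + 1e-12))
    expect_lte(min(swarm$fit), best_prev)   # elitism
  }
})

test_that("iterated genetic passes improve the best fitness", {
  f <- benchmark_function("sphere")
  improved <- vapply(1:20, function(s) {
    cfg <- swarm_config(dim = 1, lower = -100, upper = 100, mode = "GA",
                        trials = 1, seed = 500 + s)
    tr <- optimize_swarm(f, cfg)
    tr$gbest_fitness < tr$gbest_trace[1]
  }, logical(1))
  expect_gte(sum(improved), 20 * 0.99)
})

test_that("trajectories are monotone and flat under constant fitness", {
  flat <- function(X) rep(1, nrow(rbind(X)))
  attr(flat, "vectorized") <- TRUE
  for (m in c("GA", "PSO", "AsyLnCPSO", "AsyLnCPSO-GA")) {
    cfg <- swarm_config(dim = 3, lower = -1, upper = 1, iterations = 20,
                        mode = m, seed = 2)
    tr <- optimize_swarm(flat, cfg)
    expect_equal(tr$gbest_trace, rep(1, 20))
  }
  f <- benchmark_function("sphere")
  for (m in c("GA", "PSO", "AsyLnCPSO", "AsyLnCPSO-GA")) {
    cfg <- swarm_config(dim = 5, lower = -100, upper = 100,
                        iterations = 60, mode = m, seed = 4)
    tr <- optimize_swarm(f, cfg)
    expect_true(all(diff(tr$gbest_trace) <= 0))  # minimization: nonincreasing
  }
  # maximization flips the monotonicity
  cfg <- swarm_config(dim = 3, lower = -5, upper = 5, iterations = 40,
                      mode = "AsyLnCPSO-GA", direction = "maximize", seed = 6)
  g <- function(X) -benchmark_function("sphere")(X)
  attr(g, "vectorized") <- TRUE
  tr <- optimize_swarm(g, cfg)
  expect_true(all(diff(tr$gbest_trace) >= 0))
})

test_that("identical seed and config reproduce a bit-identical trajectory", {
  f <- benchmark_function("rastrigin")
  cfg <- swarm_config(dim = 6, lower = -5.12, upper = 5.12,
                      iterations = 50, mode = "AsyLnCPSO-GA", seed = 77)
  a <- optimize_swarm(f, cfg)
  b <- optimize_swarm(f, cfg)
  expect_identical(a$gbest_trace, b$gbest_trace)
  expect_identical(a$gbest_position, b$gbest_position)
})

test_that("hybrid per-iteration evaluation cost matches the operator budget", {
  f <- benchmark_function("sphere")
  cfg <- swarm_config(dim = 5, lower = -10, upper = 10, iterations = 200,
                      mode = "AsyLnCPSO-GA", seed = 12)
  tr <- optimize_swarm(f, cfg)
  per_iter <- (tr$n_evals - cfg$pop_size) / cfg$iterations  # minus init
  budget <- cfg$pop_size * (1 + cfg$crossover_rate + cfg$mutation_rate)
  expect_lt(abs(per_iter - budget), 1.5)  # rounding of the operator counts
})

test_that("non-finite fitness is absorbed as worst-possible", {
  f <- function(x) if (abs(x[1]) < 0.5) NaN else sum(x^2)
  cfg <- swarm_config(dim = 2, lower = -1, upper = 1, iterations = 30,
                      mode = "PSO", seed = 3)
  expect_message(tr <- optimize_swarm(f, cfg), "non-finite")
  expect_true(is.finite(tr$gbest_fitness))
  expect_gte(abs(tr$gbest_position[1]), 0.5)
})

test_that("trial summaries aggregate exactly", {
  f <- benchmark_function("sphere")
  cfg <- swarm_config(dim = 3, lower = -10, upper = 10, iterations = 30,
                      trials = 1, mode = "PSO", seed = 55)
  one <- run_trials(f, cfg)
  solo <- optimize_swarm(f, cfg)
  expect_equal(one$min, solo$gbest_fitness)
  expect_equal(one$mean, solo$gbest_fitness)
  expect_equal(one$mean_trace, solo$gbest_trace)

  cfg$trials <- 6
  many <- run_trials(f, cfg)
  expect_length(many$best_fitness, 6)
  expect_true(many$min <= many$mean && many$mean <= many$max)
  expect_error({ bad <- cfg; bad$trials <- 0; run_trials(f, bad) })
})
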