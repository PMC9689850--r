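#' Configuration for the swarm/genetic optimizers
#'
#' Collects population, schedule and operator settings shared by the four
#' optimizer modes: plain `"GA"`, plain `"PSO"` (constant learning factors),
#' `"AsyLnCPSO"` (PSO with asynchronously scheduled learning factors: the
#' cognitive factor c1 shrinks linearly while the social factor c2 grows),
#' and the hybrid `"AsyLnCPSO-GA"` (each iteration applies the scheduled PSO
#' update, then GA selection/crossover/mutation over all particles).
#'
#' @param dim problem dimension (length of a particle position).
#' @param lower,upper position bounds (scalar or length-`dim`).
#' @param pop_size swarm/population size (default 30).
#' @param iterations number of iterations (default 200).
#' @param trials number of independent repetitions in [run_trials()]
#'   (default 20).
#' @param w inertia weight (default 0.8).
#' @param c1,c2 constant learning factors for plain PSO (default 2.0 each).
#' @param c1_start,c1_end,c2_start,c2_end endpoints of the linear
#'   asynchronous schedules (defaults 2.5 -> 0.5 and 0.5 -> 2.5).
#' @param v_max velocity clamp; default 0.2 x the bound width per dimension.
#' @param crossover_rate fraction of the population recombined per GA pass
#'   (default 0.5).
#' @param mutation_rate fraction of the population mutated per GA pass
#'   (default 0.01); mutation adds Gaussian noise scaled to the population's
#'   per-gene dispersion.
#' @param mutation_sigma fixed per-gene mutation SD; `NULL` (default) uses
#'   the adaptive dispersion-scaled SD.
#' @param mode optimizer mode (see above).
#' @param direction `"minimize"` or `"maximize"`.
#' @param seed integer seed; identical seed + config gives a bit-identical
#'   trajectory.
#' @return a list of class `swarm_config`.
#' @export
swarm_config <- function(dim, lower, upper,
                         pop_size = 30, iterations = 200, trials = 20,
                         w = 0.8, c1 = 2, c2 = 2,
                         c1_start = 2.5, c1_end = 0.5,
                         c2_start = 0.5, c2_end = 2.5,
                         v_max = NULL,
                         crossover_rate = 0.5, mutation_rate = 0.01,
                         mutation_sigma = NULL,
                         mode = c("AsyLnCPSO-GA", "GA", "PSO", "AsyLnCPSO"),
                         direction = c("minimize", "maximize"),
                         seed = 1L) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(pop_size >= 2, iterations >= 0, trials >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  stopifnot(all(upper > lower))
  if (is.null(v_max)) v_max <- 0.2 * (upper - lower)
  v_max <- rep_len(as.numeric(v_max), dim)
  structure(list(dim = dim, lower = lower, upper = upper,
                 pop_size = pop_size, iterations = iterations,
                 trials = trials, w = w, c1 = c1, c2 = c2,
                 c1_start = c1_start, c1_end = c1_end,
                 c2_start = c2_start, c2_end = c2_end, v_max = v_max,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 mode = mode, direction = direction,
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Benchmark test functions for optimizer validation
#'
#' Standard minimization benchmarks: `rastrigin`
#' (`10 d + sum(x^2 - 10 cos(2 pi x))`, domain ±5.12), `sphere`
#' (`sum(x^2)`, ±100), `rosenbrock`
#' (`sum(100 (x_{i+1} - x_i^2)^2 + (1 - x_i)^2)`, ±30) and the shifted
#' `schwefel` (`418.9829 d - sum(x sin(sqrt(|x|)))`, ±500), all with global
#' minimum ~0.
#'
#' @param name one of `"rastrigin"`, `"sphere"`, `"rosenbrock"`,
#'   `"schwefel"`.
#' @param x numeric vector, or matrix with one point per row.
#' @return `benchmark()` returns the function value(s);
#'   `benchmark_function()` returns the vectorized function with a
#'   `"bounds"` attribute.
#' @export
benchmark_function <- function(name = c("rastrigin", "sphere", "rosenbrock",
                                        "schwefel")) {
  name <- match.arg(name)
  f <- switch(name,
    rastrigin = function(X) {
      X <- rbind(X)
      10 * ncol(X) + rowSums(X^2 - 10 * cos(2 * pi * X))
    },
    sphere = function(X) rowSums(rbind(X)^2),
    rosenbrock = function(X) {
      X <- rbind(X)
      d <- ncol(X)
      a <- X[, -d, drop = FALSE]; b <- X[, -1, drop = FALSE]
      rowSums(100 * (b - a^2)^2 + (1 - a)^2)
    },
    schwefel = function(X) {
      X <- rbind(X)
      418.9829 * ncol(X) - rowSums(X * sin(sqrt(abs(X))))
    })
  attr(f, "vectorized") <- TRUE
  attr(f, "bounds") <- switch(name,
    rastrigin = c(-5.12, 5.12), sphere = c(-100, 100),
    rosenbrock = c(-30, 30), schwefel = c(-500, 500))
  attr(f, "name") <- name
  f
}

#' @rdname benchmark_function
#' @export
benchmark <- function(name, x) {
  f <- benchmark_function(name)
  unname(f(rbind(x)))
}

#' Asynchronous learning-factor schedule
#'
#' Linear interpolation of the PSO learning factors over the run: the
#' cognitive factor decreases `c1_start -> c1_end` while the social factor
#' increases `c2_start -> c2_end`, exact at `t = 0` and `t = T`.
#'
#' @param t current iteration (0-based).
#' @param total total iterations (> 0).
#' @param config a [swarm_config].
#' @return named numeric vector `c(c1, c2)`.
#' @export
asylncpso_schedule <- function(t, total, config) {
  if (total <= 0) stop("total iterations must be positive")
  frac <- t / total
  c(c1 = config$c1_start + (config$c1_end - config$c1_start) * frac,
    c2 = config$c2_start + (config$c2_end - config$c2_start) * frac)
}

# ---- internal swarm machinery (always minimizes) -------------------------

eval_population <- function(f, X, state) {
  v <- if (isTRUE(attr(f, "vectorized"))) as.numeric(f(X))
       else apply(X, 1L, function(row) as.numeric(f(row))[1])
  bad <- !is.finite(v)
  if (any(bad)) {
    state$n_nonfinite <- state$n_nonfinite + sum(bad)
    v[bad] <- Inf  # worst possible under minimization
  }
  state$n_evals <- state$n_evals + nrow(X)
  v
}

init_swarm <- function(f, config, state) {
  p <- config$pop_size; d <- config$dim
  pos <- matrix(stats::runif(p * d), p, d)
  pos <- sweep(sweep(pos, 2, config$upper - config$lower, "*"),
               2, config$lower, "+")
  vel <- matrix(stats::runif(p * d, -1, 1), p, d)
  vel <- sweep(vel, 2, config$v_max, "*")
  fit <- eval_population(f, pos, state)
  list(pos = pos, vel = vel, fit = fit,
       pbest_pos = pos, pbest_fit = fit,
       gbest_pos = pos[which.min(fit), ], gbest_fit = min(fit))
}

clip_rows <- function(X, lower, upper) {
  X <- sweep(X, 2, upper, pmin)
  sweep(X, 2, lower, pmax)
}

#' One canonical PSO update of a swarm
#'
#' Velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' per-component clamping to `v_max`, position update with clipping to the
#' bounds, re-evaluation, and refresh of personal and global bests. Operates
#' on the internal swarm state; exposed mainly for testing and for building
#' custom loops.
#'
#' @param swarm internal swarm state as created by [optimize_swarm()].
#' @param f fitness function (minimized).
#' @param config a [swarm_config].
#' @param c1,c2 learning factors for this step.
#' @param state environment accumulating evaluation counts.
#' @return the updated swarm state.
#' @export
pso_step <- function(swarm, f, config, c1 = config$c1, c2 = config$c2,
                     state = new.env()) {
  if (is.null(state$n_evals)) { state$n_evals <- 0; state$n_nonfinite <- 0 }
  p <- config$pop_size; d <- config$dim
  r1 <- matrix(stats::runif(p * d), p, d)
  r2 <- matrix(stats::runif(p * d), p, d)
  vel <- config$w * swarm$vel +
    c1 * r1 * (swarm$pbest_pos - swarm$pos) +
    c2 * r2 * (matrix(swarm$gbest_pos, p, d, byrow = TRUE) - swarm$pos)
  vel <- sweep(vel, 2, config$v_max, function(v, m) pmin(pmax(v, -m), m))
  pos <- clip_rows(swarm$pos + vel, config$lower, config$upper)
  fit <- eval_population(f, pos, state)
  swarm$vel <- vel; swarm$pos <- pos; swarm$fit <- fit
  improved <- fit < swarm$pbest_fit
  swarm$pbest_pos[improved, ] <- pos[improved, ]
  swarm$pbest_fit[improved] <- fit[improved]
  if (min(fit) < swarm$gbest_fit) {
    swarm$gbest_fit <- min(fit)
    swarm$gbest_pos <- pos[which.min(fit), ]
  }
  swarm
}

# stochastic rounding so that expected counts match rate * pop exactly
stoch_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (stats::runif(1) < (x - fl)))
}

#' One genetic-algorithm pass over a population
#'
#' Steady-state genetic pass: `crossover_rate * pop_size` parents are drawn
#' by size-2 tournaments and recombined in pairs by uniform gene exchange
#' (each crossed gene is either swapped between the parents or blended with
#' a random BLX-style weight); a `mutation_rate` fraction of individuals
#' receives Gaussian per-gene noise, scaled by default to the population's
#' per-gene dispersion (floored at 1% of the bound width) so mutation
#' anneals as the population converges. Offspring replace their parent only
#' when strictly better, so no individual ever worsens and the best
#' individual always survives (elitism). Recombination acts on the
#' particles' personal-best memory — the "optimized particles" — which
#' keeps the pass coherent when it follows a swarm update. Only offspring
#' and mutants are evaluated: `(crossover_rate + mutation_rate) * pop_size`
#' fitness evaluations per pass up to rounding.
#'
#' @inheritParams pso_step
#' @return the updated swarm state (positions, fitness, bests refreshed).
#' @export
ga_operate <- function(swarm, f, config, state = new.env()) {
  if (is.null(state$n_evals)) { state$n_evals <- 0; state$n_nonfinite <- 0 }
  p <- config$pop_size; d <- config$dim

  # tournament parent selection (size 2) + uniform swap/blend crossover
  nc <- round(config$crossover_rate * p)
  nc <- nc - nc %% 2L
  if (nc >= 2) {
    a <- sample.int(p, nc, replace = TRUE)
    b <- sample.int(p, nc, replace = TRUE)
    par <- ifelse(swarm$fit[a] <= swarm$fit[b], a, b)
    child <- matrix(0, nc, d)
    for (k in seq(1, nc, by = 2)) {
      gi <- swarm$pbest_pos[par[k], ]
      gj <- swarm$pbest_pos[par[k + 1], ]
      cross <- stats::runif(d) < 0.5         # genes taking part
      swap  <- stats::runif(d) < 0.5         # swap vs blend per gene
      beta  <- stats::runif(d, -0.25, 1.25)  # BLX-style blend weight
      mi <- ifelse(swap, gj, beta * gi + (1 - beta) * gj)
      mj <- ifelse(swap, gi, beta * gj + (1 - beta) * gi)
      ci <- gi; cj <- gj
      ci[cross] <- mi[cross]; cj[cross] <- mj[cross]
      child[k, ] <- ci; child[k + 1, ] <- cj
    }
    child <- clip_rows(child, config$lower, config$upper)
    cf <- eval_population(f, child, state)
    for (k in seq_len(nc)) {           # greedy replacement of the parent
      i <- par[k]
      if (cf[k] < swarm$fit[i]) {
        swarm$pos[i, ] <- child[k, ]
        swarm$fit[i] <- cf[k]
      }
    }
  }

  # Gaussian per-gene mutation of a mutation_rate fraction of individuals
  nm <- stoch_round(config$mutation_rate * p)
  if (nm >= 1) {
    sigma <- if (is.null(config$mutation_sigma))
      pmax(apply(swarm$pos, 2, stats::sd),
           0.01 * (config$upper - config$lower), 1e-12)
    else rep_len(config$mutation_sigma, d)
    idx <- sample.int(p, nm)
    noise <- matrix(stats::rnorm(nm * d), nm, d)
    mut <- swarm$pos[idx, , drop = FALSE] + sweep(noise, 2, sigma, "*")
    mut <- clip_rows(mut, config$lower, config$upper)
    mf <- eval_population(f, mut, state)
    for (k in seq_len(nm)) {
      i <- idx[k]
      if (mf[k] < swarm$fit[i]) {
        swarm$pos[i, ] <- mut[k, ]
        swarm$fit[i] <- mf[k]
      }
    }
  }

  improved <- swarm$fit < swarm$pbest_fit
  swarm$pbest_pos[improved, ] <- swarm$pos[improved, , drop = FALSE]
  swarm$pbest_fit[improved] <- swarm$fit[improved]
  if (min(swarm$fit) < swarm$gbest_fit) {
    swarm$gbest_fit <- min(swarm$fit)
    swarm$gbest_pos <- swarm$pos[which.min(swarm$fit), ]
  }
  swarm
}

#' Run one optimization trajectory
#'
#' Iterates the operator(s) selected by `config$mode` and tracks the global
#' best across them: `"GA"` applies only the genetic pass, `"PSO"` the
#' canonical update with constant factors, `"AsyLnCPSO"` the update with the
#' asynchronous linear schedule, and `"AsyLnCPSO-GA"` the scheduled update
#' followed by the genetic pass over all particles in every iteration.
#' Non-finite fitness values are treated as worst-possible. With
#' `iterations = 0` the result is the best of the random initial population.
#'
#' @param fitness function mapping a length-`dim` numeric vector to a
#'   scalar; give it attribute `vectorized = TRUE` if it accepts a matrix of
#'   row-vectors.
#' @param config a [swarm_config]; `config$direction` selects minimization
#'   or maximization, `config$seed` makes the run reproducible.
#' @return a list of class `swarm_trajectory`: `gbest_trace` (best fitness
#'   after each iteration, in the user's direction), `gbest_fitness`,
#'   `gbest_position`, `n_evals`, `n_nonfinite`, `elapsed_s`, `mode`.
#' @export
optimize_swarm <- function(fitness, config) {
  stopifnot(inherits(config, "swarm_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  sign <- if (config$direction == "maximize") -1 else 1
  f <- if (sign < 0) {
    g <- function(X) -fitness(X)
    attributes(g) <- attributes(fitness)
    g
  } else fitness
  state <- new.env()
  state$n_evals <- 0; state$n_nonfinite <- 0
  swarm <- init_swarm(f, config, state)
  trace <- numeric(config$iterations)
  Tn <- config$iterations
  for (t in seq_len(Tn)) {
    swarm <- switch(config$mode,
      "GA" = ga_operate(swarm, f, config, state),
      "PSO" = pso_step(swarm, f, config, config$c1, config$c2, state),
      "AsyLnCPSO" = {
        cc <- asylncpso_schedule(t, Tn, config)
        pso_step(swarm, f, config, cc[1], cc[2], state)
      },
      "AsyLnCPSO-GA" = {
        cc <- asylncpso_schedule(t, Tn, config)
        s <- pso_step(swarm, f, config, cc[1], cc[2], state)
        ga_operate(s, f, config, state)
      })
    trace[t] <- sign * swarm$gbest_fit
  }
  if (state$n_nonfinite > 0)
    message(state$n_nonfinite, " non-finite fitness value(s) treated as worst-possible")
  structure(list(gbest_trace = trace,
                 gbest_fitness = sign * swarm$gbest_fit,
                 gbest_position = swarm$gbest_pos,
                 n_evals = state$n_evals,
                 n_nonfinite = state$n_nonfinite,
                 elapsed_s = proc.time()[["elapsed"]] - t0,
                 mode = config$mode),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: best fitness %.6g after %d evaluations (%.2f s)\n",
              x$mode, x$gbest_fitness, x$n_evals, x$elapsed_s))
  invisible(x)
}

#' Repeat an optimization over independent trials
#'
#' Runs [optimize_swarm()] `config$trials` times with per-trial seeds derived
#' from `config$seed` and aggregates the final best fitness values.
#'
#' @inheritParams optimize_swarm
#' @return list of class `trial_summary`: `best_fitness` (per trial), `min`,
#'   `max`, `mean`, `mean_time_s`, `mean_trace` (iteration-wise mean of the
#'   best-so-far curves) and `trajectories`.
#' @export
run_trials <- function(fitness, config) {
  stopifnot(inherits(config, "swarm_config"))
  if (config$trials < 1) stop("need at least one trial")
  trajs <- vector("list", config$trials)
  for (k in seq_len(config$trials)) {
    ck <- config
    ck$seed <- config$seed + (k - 1L)
    trajs[[k]] <- optimize_swarm(fitness, ck)
  }
  best <- vapply(trajs, function(tr) tr$gbest_fitness, numeric(1))
  traces <- vapply(trajs, function(tr) tr$gbest_trace,
                   numeric(config$iterations))
  structure(list(best_fitness = best,
                 min = min(best), max = max(best), mean = mean(best),
                 mean_time_s = mean(vapply(trajs, function(tr) tr$elapsed_s,
                                           numeric(1))),
                 mean_trace = if (config$iterations > 0)
                   rowMeans(matrix(traces, nrow = config$iterations))
                 else numeric(0),
                 trajectories = trajs),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("%d trials: min %.6g / mean %.6g / max %.6g (mean %.2f s)\n",
              length(x$best_fitness), x$min, x$mean, x$max, x$mean_time_s))
  invisible(x)
}
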