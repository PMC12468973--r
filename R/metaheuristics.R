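# Binary-encoded metaheuristic wrappers. The three optimizers search the
# continuous relaxation [0,1]^d; candidate positions are squashed through a
# logistic transfer function and thresholded to a feature mask before each
# fitness call. All three use greedy per-member acceptance plus a global
# elite, so the best-so-far trace is nonincreasing by construction.

#' Configuration of a metaheuristic feature-selection run
#'
#' @param pop_size Population size. Default 20.
#' @param iterations Number of iterations. Default 50.
#' @param runs Independent seeded runs for [run_multi()]. Default 10.
#' @param seeds Optional integer vector of per-run seeds (length `runs`).
#' @param threshold Binarization threshold on the transfer output.
#'   Default 0.5, with a strict inequality, so a position of exactly 0.5
#'   deselects its feature.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(pop_size = 20L, iterations = 50L, runs = 10L,
                             seeds = NULL, threshold = 0.5) {
  stopifnot(pop_size >= 2, iterations >= 1, runs >= 1)
  if (!is.null(seeds)) stopifnot(length(seeds) == runs)
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 runs = as.integer(runs), seeds = seeds,
                 threshold = threshold),
            class = "optimizer_config")
}

#' Continuous-to-binary transfer
#'
#' Logistic sigmoid centered at 0.5 (steepness 10); a feature is selected
#' iff the transferred position strictly exceeds the threshold. Because the
#' transfer is strictly increasing with transfer(0.5) = 0.5, the default
#' rule reduces to `position > 0.5`.
#'
#' @param position Numeric vector in `[0, 1]^d` (finite values required).
#' @param threshold Selection threshold in (0, 1). Default 0.5.
#' @return Integer 0/1 mask.
#' @export
binarize <- function(position, threshold = 0.5) {
  if (any(!is.finite(position))) abort("Non-finite position component.")
  transfer <- 1 / (1 + exp(-10 * (position - 0.5)))
  as.integer(transfer > threshold)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

levy_step <- function(d, beta = 1.5) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(d) * sigma
  v <- rnorm(d)
  0.01 * u / abs(v)^(1 / beta)
}

# Shared driver state: evaluate a candidate position, with greedy acceptance
# handled by the callers.
make_evaluator <- function(fitness, threshold) {
  force(fitness); force(threshold)
  function(position) fitness(binarize(position, threshold))
}

new_candidate <- function(position, threshold, fitness_value) {
  structure(list(position = position,
                 mask = binarize(position, threshold),
                 fitness = fitness_value),
            class = "candidate")
}

init_population <- function(pop, d, eval_fn) {
  x <- matrix(runif(pop * d), pop, d)
  f <- apply(x, 1, eval_fn)
  list(x = x, f = f)
}

# Greedy acceptance of a proposed position for member i.
accept_if_better <- function(state, i, proposal, eval_fn) {
  proposal <- clamp01(proposal)
  fp <- eval_fn(proposal)
  if (fp < state$f[i]) {
    state$x[i, ] <- proposal
    state$f[i] <- fp
  }
  state
}

finalize_run <- function(state, trace, threshold) {
  best <- which.min(state$f)
  list(best = new_candidate(state$x[best, ], threshold, state$f[best]),
       trace = trace)
}

#' Harris Hawks optimization of a binary feature mask
#'
#' Canonical Harris Hawks Optimization adapted to wrapper feature selection:
#' perch-based exploration while the prey's escape energy |E| >= 1, then
#' soft/hard besiege and Levy-flight rapid dives as the energy
#' `E = 2 E0 (1 - t/T)` decays. Positions live in `[0,1]^d` and are
#' binarized for every fitness evaluation; proposals are accepted greedily.
#'
#' @param config An [optimizer_config()].
#' @param fitness Function mapping a 0/1 mask of length `d` to an error in
#'   `[0, 1]` (see [fitness_error()]).
#' @param d Dimension of the mask space.
#' @param seed Integer seed.
#' @return List with `best` (a candidate: `position`, `mask`, `fitness`)
#'   and `trace` (best-so-far fitness per iteration, nonincreasing).
#' @export
run_hho <- function(config, fitness, d, seed = 1L) {
  stopifnot(d >= 1)
  local_seed(seed)
  eval_fn <- make_evaluator(fitness, config$threshold)
  st <- init_population(config$pop_size, d, eval_fn)
  trace <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    best_i <- which.min(st$f)
    x_best <- st$x[best_i, ]
    x_mean <- colMeans(st$x)
    e1 <- 2 * (1 - t / config$iterations)
    for (i in seq_len(config$pop_size)) {
      e0 <- runif(1, -1, 1)
      e <- e1 * e0
      jump <- 2 * (1 - runif(1))
      xi <- st$x[i, ]
      if (abs(e) >= 1) {
        # exploration: perch on a random hawk or on the family's mean
        if (runif(1) >= 0.5) {
          xr <- st$x[sample.int(config$pop_size, 1), ]
          prop <- xr - runif(1) * abs(xr - 2 * runif(1) * xi)
        } else {
          prop <- (x_best - x_mean) - runif(1) * runif(1)
        }
        st <- accept_if_better(st, i, prop, eval_fn)
      } else {
        r <- runif(1)
        if (r >= 0.5 && abs(e) >= 0.5) {        # soft besiege
          prop <- (x_best - xi) - e * abs(jump * x_best - xi)
          st <- accept_if_better(st, i, prop, eval_fn)
        } else if (r >= 0.5) {                  # hard besiege
          prop <- x_best - e * abs(x_best - xi)
          st <- accept_if_better(st, i, prop, eval_fn)
        } else if (abs(e) >= 0.5) {             # soft besiege, rapid dives
          y <- x_best - e * abs(jump * x_best - xi)
          z <- y + runif(d) * levy_step(d)
          st <- accept_if_better(st, i, y, eval_fn)
          st <- accept_if_better(st, i, z, eval_fn)
        } else {                                # hard besiege, rapid dives
          y <- x_best - e * abs(jump * x_best - x_mean)
          z <- y + runif(d) * levy_step(d)
          st <- accept_if_better(st, i, y, eval_fn)
          st <- accept_if_better(st, i, z, eval_fn)
        }
      }
    }
    trace[t] <- min(st$f)
  }
  finalize_run(st, trace, config$threshold)
}

#' Modified Gorilla Troops optimization of a binary feature mask
#'
#' Gorilla Troops Optimizer with its two-stage iteration: exploration
#' (migration to an unknown place with probability `p`, movement toward a
#' random troop member, or a combined migration) followed by exploitation
#' (follow-the-silverback when the control parameter C is large, adult
#' competition otherwise). The "modified" refinement replaces the linear
#' decay of C with a cosine decay, holding exploration longer early and
#' sharpening exploitation late. Greedy acceptance; binarized evaluation.
#'
#' @inheritParams run_hho
#' @return As [run_hho()].
#' @export
run_mgto <- function(config, fitness, d, seed = 1L) {
  stopifnot(d >= 1)
  local_seed(seed)
  p_migrate <- 0.03; beta <- 3; w_thresh <- 0.8
  eval_fn <- make_evaluator(fitness, config$threshold)
  st <- init_population(config$pop_size, d, eval_fn)
  trace <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    f_ctl <- cos(2 * runif(1)) + 1
    c_ctl <- f_ctl * cos(pi / 2 * t / config$iterations)  # modified decay
    l_ctl <- c_ctl * runif(1, -1, 1)
    # exploration
    for (i in seq_len(config$pop_size)) {
      xi <- st$x[i, ]
      r <- runif(1)
      if (r < p_migrate) {
        prop <- runif(d)
      } else if (r >= 0.5) {
        z <- runif(d, -c_ctl, c_ctl)
        xr <- st$x[sample.int(config$pop_size, 1), ]
        prop <- (runif(1) - c_ctl) * xr + l_ctl * (z * xi)
      } else {
        xr <- st$x[sample.int(config$pop_size, 1), ]
        prop <- xi - l_ctl * (l_ctl * (xi - xr) + runif(1) * (xi - xr))
      }
      st <- accept_if_better(st, i, prop, eval_fn)
    }
    # exploitation
    x_best <- st$x[which.min(st$f), ]
    for (i in seq_len(config$pop_size)) {
      xi <- st$x[i, ]
      if (c_ctl >= w_thresh) {
        g <- 2^l_ctl
        m <- (abs(colMeans(st$x))^g)^(1 / g)
        prop <- l_ctl * m * (xi - x_best) + xi
      } else {
        q <- 2 * runif(1) - 1
        a2 <- beta * rnorm(1)
        prop <- x_best - (x_best * q - xi * q) * a2
      }
      st <- accept_if_better(st, i, prop, eval_fn)
    }
    trace[t] <- min(st$f)
  }
  finalize_run(st, trace, config$threshold)
}

#' Zebra optimization of a binary feature mask
#'
#' Zebra Optimization Algorithm: a foraging phase where each zebra moves
#' toward the pioneer (population best), and a defense phase that either
#' flees a lion-style attack (small local escape shrinking over time) or
#' converges toward a randomly attacked herd member. Greedy acceptance;
#' binarized evaluation.
#'
#' @inheritParams run_hho
#' @return As [run_hho()].
#' @export
run_zoa <- function(config, fitness, d, seed = 1L) {
  stopifnot(d >= 1)
  local_seed(seed)
  r_escape <- 0.01
  eval_fn <- make_evaluator(fitness, config$threshold)
  st <- init_population(config$pop_size, d, eval_fn)
  trace <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    pioneer <- st$x[which.min(st$f), ]
    for (i in seq_len(config$pop_size)) {     # phase 1: foraging
      ii <- round(1 + runif(1))
      prop <- st$x[i, ] + runif(d) * (pioneer - ii * st$x[i, ])
      st <- accept_if_better(st, i, prop, eval_fn)
    }
    for (i in seq_len(config$pop_size)) {     # phase 2: defense
      if (runif(1) <= 0.5) {
        prop <- st$x[i, ] +
          r_escape * (2 * runif(d) - 1) * (1 - t / config$iterations) * st$x[i, ]
      } else {
        az <- st$x[sample.int(config$pop_size, 1), ]
        ii <- round(1 + runif(1))
        prop <- st$x[i, ] + runif(d) * (az - ii * st$x[i, ])
      }
      st <- accept_if_better(st, i, prop, eval_fn)
    }
    trace[t] <- min(st$f)
  }
  finalize_run(st, trace, config$threshold)
}

#' Run one optimizer by name
#'
#' @param algorithm One of `"hho"`, `"mgto"`, `"zoa"`.
#' @inheritParams run_hho
#' @return As [run_hho()].
#' @export
run_optimizer <- function(algorithm = c("hho", "mgto", "zoa"), config,
                          fitness, d, seed = 1L) {
  algorithm <- match.arg(algorithm)
  fn <- switch(algorithm, hho = run_hho, mgto = run_mgto, zoa = run_zoa)
  fn(config, fitness, d, seed = seed)
}

#' Repeated seeded runs of one optimizer
#'
#' Executes `config$runs` independent runs with distinct seeds and reports
#' each run's best mask and wrapper accuracy (`1 - fitness`), plus their
#' mean and standard deviation.
#'
#' @inheritParams run_optimizer
#' @param seed Master seed used to derive per-run seeds when `config$seeds`
#'   is not supplied.
#' @return List with `runs` (tibble: run, seed, best_fitness, accuracy,
#'   n_selected), `masks` (list of best masks), `traces` (list of traces),
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
run_multi <- function(algorithm, config, fitness, d, seed = 1L) {
  seeds <- config$seeds %||% vapply(seq_len(config$runs),
                                    function(r) derive_seed(seed, r), integer(1))
  results <- map(seeds, function(s) run_optimizer(algorithm, config, fitness, d, seed = s))
  acc <- map_dbl(results, ~ 1 - .x$best$fitness)
  list(
    runs = tibble(run = seq_along(seeds), seed = as.integer(seeds),
                  best_fitness = map_dbl(results, ~ .x$best$fitness),
                  accuracy = acc,
                  n_selected = map_int(results, ~ sum(.x$best$mask))),
    masks = map(results, ~ .x$best$mask),
    traces = map(results, ~ .x$trace),
    mean_accuracy = mean(acc),
    sd_accuracy = if (length(acc) > 1) sd(acc) else 0
  )
}
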