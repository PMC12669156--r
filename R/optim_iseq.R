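#' Box-constrained search space
#'
#' @param lower,upper numeric bound vectors of equal length (`lower < upper`
#'   elementwise). Scalars are recycled to `dim`.
#' @param dim dimensionality (defaults to `length(lower)`).
#' @param discrete if `TRUE` the space is interpreted as a bit-mask space:
#'   positions are mapped to bits through a sigmoid transfer function.
#' @return object of class `search_space`.
#' @export
search_space <- function(lower, upper, dim = length(lower), discrete = FALSE) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  stopifnot(all(lower < upper))
  structure(list(dim = dim, lower = lower, upper = upper, discrete = discrete),
            class = "search_space")
}

#' Optimizer configuration
#'
#' @param pop_size number of agents (>= 2).
#' @param max_iters generations (>= 1).
#' @param seed integer seed; identical config + seed reproduces the run.
#' @param levy_beta Levy stability index in (1, 2]; 1.5 by default
#'   (Mantegna's standard choice).
#' @param alpha0 initial Levy step scale as a fraction of the box range.
#' @param renewal_fraction fraction of worst agents chaotically
#'   reinitialised each generation ("fire renewal").
#' @param chaotic_init logistic-map chaotic initialisation (on for
#'   ISequoiaOA; the plain SequoiaOA baseline switches it off).
#' @param decay_steps if `TRUE` (ISequoiaOA) the Levy step scale decays as
#'   `exp(-4 t / T)`; if `FALSE` (SequoiaOA) it stays fixed at `alpha0`.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 30L, max_iters = 500L, seed = 1L,
                             levy_beta = 1.5, alpha0 = 0.1,
                             renewal_fraction = 0.1, chaotic_init = TRUE,
                             decay_steps = TRUE) {
  stopifnot(pop_size >= 2, max_iters >= 1,
            levy_beta > 1, levy_beta <= 2,
            renewal_fraction >= 0, renewal_fraction < 1)
  structure(list(pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters),
                 seed = as.integer(seed), levy_beta = levy_beta,
                 alpha0 = alpha0, renewal_fraction = renewal_fraction,
                 chaotic_init = isTRUE(chaotic_init),
                 decay_steps = isTRUE(decay_steps)),
            class = "optimizer_config")
}

#' Logistic-map chaotic sequence
#'
#' Iterates the fully chaotic logistic map `x <- 4 x (1 - x)`. Its orbit is
#' ergodic with the arcsine (Beta(1/2, 1/2)) invariant density, spreading
#' initial agents more evenly towards the box faces than uniform draws.
#' Degenerate starting points whose orbits collapse (0, 1/4, 1/2, 3/4, 1)
#' are rejected.
#'
#' @param x0 starting value in (0, 1), not a degenerate orbit point.
#' @param n sequence length.
#' @return numeric vector of `n` values in (0, 1).
#' @export
logistic_chaos_sequence <- function(x0, n) {
  if (x0 <= 0 || x0 >= 1 || x0 %in% c(0.25, 0.5, 0.75)) {
    stop("degenerate chaotic seed x0 = ", x0, "; redraw from (0,1)",
         call. = FALSE)
  }
  out <- numeric(n)
  x <- x0
  for (i in seq_len(n)) {
    x <- 4 * x * (1 - x)
    out[i] <- x
  }
  out
}

# draw a non-degenerate chaos seed from the current RNG stream
draw_chaos_seed <- function() {
  repeat {
    x0 <- stats::runif(1)
    if (x0 > 1e-6 && x0 < 1 - 1e-6 && !x0 %in% c(0.25, 0.5, 0.75)) return(x0)
  }
}

#' Initialise an optimizer population
#'
#' Chaotic mode runs one logistic-map orbit per dimension (independent
#' random starting points) and scales it into the bounds; uniform mode uses
#' plain uniform draws. Both are deterministic given the config seed.
#'
#' @param space a `search_space`.
#' @param config an `optimizer_config`.
#' @return `pop_size` x `dim` position matrix inside the bounds.
#' @export
init_population <- function(space, config) {
  with_seed(config$seed, init_population_(space, config$pop_size,
                                          config$chaotic_init))
}

init_population_ <- function(space, n, chaotic) {
  d <- space$dim
  if (chaotic) {
    # chaotic Latin hypercube: one logistic orbit per dimension supplies
    # the within-stratum jitter (uniformised through the arcsine CDF of
    # the map's invariant density), a seeded permutation the strata —
    # marginals are stratified, so agents spread wider than iid uniform
    u <- vapply(seq_len(d), function(j) {
      orbit <- logistic_chaos_sequence(draw_chaos_seed(), n)
      jitter <- 2 / pi * asin(sqrt(orbit))
      (sample(n) - 1 + jitter) / n
    }, numeric(n))
    u <- matrix(u, n, d)
  } else {
    u <- matrix(stats::runif(n * d), n, d)
  }
  sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

#' Mantegna sigma for Levy-stable steps
#'
#' @param beta stability index in (1, 2].
#' @return the numerator-normal scale `sigma_u`.
#' @export
levy_sigma <- function(beta) {
  stopifnot(beta > 1, beta <= 2)
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Mantegna Levy-flight steps
#'
#' Heavy-tailed steps `u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)`; the tail index equals `beta`, giving occasional long
#' jumps that help escape local optima.
#'
#' @param beta stability index in (1, 2].
#' @param n number of steps.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return numeric vector of `n` steps.
#' @export
mantegna_levy <- function(beta, n, seed = NULL) {
  draw <- function() {
    sigma <- levy_sigma(beta)
    u <- stats::rnorm(n, 0, sigma)
    v <- stats::rnorm(n)
    u / abs(v)^(1 / beta)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Levy step-scale schedule
#'
#' Exponential decay `alpha0 * exp(-4 t / T)`: wide exploratory jumps early,
#' fine exploitation steps late (about 1.8% of the initial scale at the
#' final iteration).
#'
#' @param t current iteration (0..T).
#' @param T max iterations.
#' @param alpha0 initial scale.
#' @return scalar step scale.
#' @export
step_scale <- function(t, T, alpha0) {
  stopifnot(t >= 0, t <= T)
  alpha0 * exp(-4 * t / T)
}

#' ISequoiaOA: chaotic-initialisation Levy-flight swarm minimiser
#'
#' Population metaheuristic patterned on sequoia-forest dynamics. Each
#' generation applies three phases: (i) canopy growth — every agent moves
#' towards the global best with a coefficient annealed linearly from 2 to
#' 0; (ii) seed dispersal — a random half of the agents receive a Levy
#' perturbation `alpha(t) * levy * (x - best)` whose scale decays
#' exponentially over the run; (iii) fire renewal — the worst
#' `renewal_fraction` of agents are chaotically reinitialised. Positions
#' are clipped to the box; candidates with non-finite objective values are
#' discarded with a warning.
#'
#' @param objective function mapping a numeric vector to a scalar to be
#'   minimised.
#' @param space a `search_space`.
#' @param config an `optimizer_config`.
#' @return object of class `opt_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far per iteration, non-increasing), `evals`.
#' @export
iseq_optimize <- function(objective, space, config = optimizer_config()) {
  with_seed(config$seed, iseq_core(objective, space, config))
}

eval_population <- function(objective, X) {
  f <- apply(X, 1, function(x) {
    v <- objective(x)
    if (!is.finite(v)) NA_real_ else v
  })
  if (anyNA(f)) {
    warning("non-finite objective value; candidate(s) discarded",
            call. = FALSE)
    f[is.na(f)] <- Inf
  }
  f
}

iseq_core <- function(objective, space, config) {
  n <- config$pop_size; d <- space$dim; T <- config$max_iters
  rng <- space$upper - space$lower
  X <- init_population_(space, n, config$chaotic_init)
  f <- eval_population(objective, X)
  evals <- n
  best_i <- which.min(f)
  best_x <- X[best_i, ]; best_f <- f[best_i]
  history <- numeric(T)
  alpha0 <- config$alpha0
  for (t in seq_len(T)) {
    # (i) canopy growth: contraction/overshoot around the incumbent best
    a <- 2 * (1 - t / T)
    R <- matrix(stats::runif(n * d), n, d)
    X <- X + a * R * sweep(-X, 2, best_x, "+")
    # (ii) seed dispersal: Levy perturbation of a random half of agents;
    # the step scale is in box-range units (alpha0 = 0.1 x range), so the
    # decaying schedule really does hand the end of the run to fine search
    half <- sample(n, floor(n / 2))
    if (length(half)) {
      alpha <- if (config$decay_steps) step_scale(t, T, alpha0) else alpha0
      L <- matrix(mantegna_levy(config$levy_beta, length(half) * d), length(half), d)
      X[half, ] <- X[half, , drop = FALSE] +
        alpha * L * matrix(rng, length(half), d, byrow = TRUE)
    }
    X <- sweep(sweep(X, 2, space$lower, pmax2), 2, space$upper, pmin2)
    f <- eval_population(objective, X)
    evals <- evals + n
    # (iii) fire renewal: chaotic restart of the worst agents
    k <- floor(config$renewal_fraction * n)
    if (k > 0) {
      worst <- order(f, decreasing = TRUE)[seq_len(k)]
      X[worst, ] <- init_population_(space, k, chaotic = TRUE)
      f[worst] <- eval_population(objective, X[worst, , drop = FALSE])
      evals <- evals + k
    }
    i <- which.min(f)
    if (f[i] < best_f) { best_f <- f[i]; best_x <- X[i, ] }
    history[t] <- best_f
  }
  structure(list(best_position = best_x, best_fitness = best_f,
                 history = history, evals = evals),
            class = "opt_result")
}

pmax2 <- function(x, lo) pmax(x, lo)
pmin2 <- function(x, hi) pmin(x, hi)

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("opt_result: best fitness %.6g after %d evaluations (%d iters)\n",
              x$best_fitness, x$evals, length(x$history)))
  invisible(x)
}
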