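#' Baseline swarm/evolutionary optimizers
#'
#' Standard implementations of the comparison algorithms behind the same
#' interface as [iseq_optimize()]: particle swarm optimisation (PSO,
#' constriction-free with linearly decaying inertia), a real-coded genetic
#' algorithm (GA: tournament selection, blend crossover, decaying Gaussian
#' mutation, elitism), grey-wolf optimiser (GWO), whale optimisation
#' algorithm (WOA), and the plain SequoiaOA (ISequoiaOA with uniform
#' initialisation and a fixed, non-decaying Levy step scale).
#'
#' @param algorithm one of `"PSO"`, `"GA"`, `"GWO"`, `"WOA"`, `"SequoiaOA"`,
#'   `"ISequoiaOA"`.
#' @param objective scalar function to minimise.
#' @param space a `search_space`.
#' @param config an `optimizer_config`.
#' @return an `opt_result`.
#' @export
baseline_optimize <- function(algorithm, objective, space,
                              config = optimizer_config()) {
  algorithm <- match.arg(algorithm,
                         c("PSO", "GA", "GWO", "WOA", "SequoiaOA", "ISequoiaOA"))
  if (algorithm == "ISequoiaOA") return(iseq_optimize(objective, space, config))
  if (algorithm == "SequoiaOA") {
    cfg <- config
    cfg$chaotic_init <- FALSE
    cfg$decay_steps <- FALSE
    return(iseq_optimize(objective, space, cfg))
  }
  core <- switch(algorithm, PSO = pso_core, GA = ga_core,
                 GWO = gwo_core, WOA = woa_core)
  with_seed(config$seed, core(objective, space, config))
}

finish_result <- function(best_x, best_f, history, evals) {
  structure(list(best_position = best_x, best_fitness = best_f,
                 history = history, evals = evals),
            class = "opt_result")
}

pso_core <- function(objective, space, config) {
  n <- config$pop_size; d <- space$dim; T <- config$max_iters
  rng <- space$upper - space$lower
  X <- init_population_(space, n, chaotic = FALSE)
  V <- matrix(0, n, d)
  f <- eval_population(objective, X); evals <- n
  P <- X; pf <- f
  g <- which.min(pf); best_x <- P[g, ]; best_f <- pf[g]
  history <- numeric(T)
  vmax <- 0.2 * rng
  for (t in seq_len(T)) {
    w <- 0.9 - 0.5 * t / T
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    V <- w * V + 1.49445 * r1 * (P - X) +
      1.49445 * r2 * sweep(-X, 2, best_x, "+")
    V <- sweep(sweep(V, 2, -vmax, pmax2), 2, vmax, pmin2)
    X <- X + V
    X <- sweep(sweep(X, 2, space$lower, pmax2), 2, space$upper, pmin2)
    f <- eval_population(objective, X); evals <- evals + n
    imp <- f < pf
    P[imp, ] <- X[imp, , drop = FALSE]; pf[imp] <- f[imp]
    g <- which.min(pf)
    if (pf[g] < best_f) { best_f <- pf[g]; best_x <- P[g, ] }
    history[t] <- best_f
  }
  finish_result(best_x, best_f, history, evals)
}

ga_core <- function(objective, space, config) {
  n <- config$pop_size; d <- space$dim; T <- config$max_iters
  rng <- space$upper - space$lower
  X <- init_population_(space, n, chaotic = FALSE)
  f <- eval_population(objective, X); evals <- n
  best_i <- which.min(f); best_x <- X[best_i, ]; best_f <- f[best_i]
  history <- numeric(T)
  for (t in seq_len(T)) {
    # binary tournament selection
    pick <- function() {
      a <- sample(n, 2)
      if (f[a[1]] <= f[a[2]]) a[1] else a[2]
    }
    newX <- matrix(0, n, d)
    newX[1, ] <- best_x                      # elitism
    for (i in 2:n) {
      p1 <- X[pick(), ]; p2 <- X[pick(), ]
      u <- stats::runif(d, -0.25, 1.25)      # BLX-style blend crossover
      child <- u * p1 + (1 - u) * p2
      mut <- stats::runif(d) < 0.15
      sdv <- 0.2 * rng * exp(-3 * t / T)     # decaying mutation scale
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sdv[mut])
      newX[i, ] <- child
    }
    X <- sweep(sweep(newX, 2, space$lower, pmax2), 2, space$upper, pmin2)
    f <- eval_population(objective, X); evals <- evals + n
    i <- which.min(f)
    if (f[i] < best_f) { best_f <- f[i]; best_x <- X[i, ] }
    history[t] <- best_f
  }
  finish_result(best_x, best_f, history, evals)
}

gwo_core <- function(objective, space, config) {
  n <- config$pop_size; d <- space$dim; T <- config$max_iters
  X <- init_population_(space, n, chaotic = FALSE)
  f <- eval_population(objective, X); evals <- n
  ord <- order(f)
  alpha <- X[ord[1], ]; beta <- X[ord[2], ]; delta <- X[ord[3], ]
  best_x <- alpha; best_f <- f[ord[1]]
  history <- numeric(T)
  for (t in seq_len(T)) {
    a <- 2 * (1 - t / T)
    for (i in seq_len(n)) {
      x <- X[i, ]
      move <- function(lead) {
        A <- a * (2 * stats::runif(d) - 1)
        C <- 2 * stats::runif(d)
        lead - A * abs(C * lead - x)
      }
      X[i, ] <- (move(alpha) + move(beta) + move(delta)) / 3
    }
    X <- sweep(sweep(X, 2, space$lower, pmax2), 2, space$upper, pmin2)
    f <- eval_population(objective, X); evals <- evals + n
    ord <- order(f)
    alpha <- X[ord[1], ]; beta <- X[ord[2], ]; delta <- X[ord[3], ]
    if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- alpha }
    history[t] <- best_f
  }
  finish_result(best_x, best_f, history, evals)
}

woa_core <- function(objective, space, config) {
  n <- config$pop_size; d <- space$dim; T <- config$max_iters
  X <- init_population_(space, n, chaotic = FALSE)
  f <- eval_population(objective, X); evals <- n
  best_i <- which.min(f); best_x <- X[best_i, ]; best_f <- f[best_i]
  history <- numeric(T)
  b <- 1
  for (t in seq_len(T)) {
    a <- 2 * (1 - t / T)
    for (i in seq_len(n)) {
      x <- X[i, ]
      p <- stats::runif(1)
      if (p < 0.5) {
        A <- a * (2 * stats::runif(d) - 1)
        C <- 2 * stats::runif(d)
        if (max(abs(A)) < 1) {
          X[i, ] <- best_x - A * abs(C * best_x - x)   # encircling
        } else {
          xr <- X[sample(n, 1), ]
          X[i, ] <- xr - A * abs(C * xr - x)           # exploration
        }
      } else {
        l <- stats::runif(1, -1, 1)                    # spiral bubble-net
        D <- abs(best_x - x)
        X[i, ] <- D * exp(b * l) * cos(2 * pi * l) + best_x
      }
    }
    X <- sweep(sweep(X, 2, space$lower, pmax2), 2, space$upper, pmin2)
    f <- eval_population(objective, X); evals <- evals + n
    i <- which.min(f)
    if (f[i] < best_f) { best_f <- f[i]; best_x <- X[i, ] }
    history[t] <- best_f
  }
  finish_result(best_x, best_f, history, evals)
}
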