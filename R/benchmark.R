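#' Built-in benchmark test functions
#'
#' Twelve standard box-constrained test functions with known global minima
#' (value 0), covering unimodal, ill-conditioned and multimodal landscapes.
#' Each function's optimum is shifted to a seeded random point inside the
#' box so that algorithms exploiting the origin gain no advantage.
#'
#' @param dim dimensionality.
#' @param shift_seed integer seed for the random optimum shifts.
#' @return named list of entries with `fn(x)`, `lower`, `upper`, `optimum`
#'   (the shift point) and `f_min` (0).
#' @export
benchmark_functions <- function(dim = 10L, shift_seed = 42L) {
  defs <- list(
    sphere       = list(b = 100, f = function(z) sum(z^2)),
    ellipsoid    = list(b = 100, f = function(z) {
      d <- length(z); sum(10^(6 * (seq_len(d) - 1) / max(d - 1, 1)) * z^2)
    }),
    rosenbrock   = list(b = 30, f = function(z) {
      zz <- z + 1  # optimum of the classic form sits at 1
      sum(100 * (zz[-1] - zz[-length(zz)]^2)^2 + (zz[-length(zz)] - 1)^2)
    }),
    rastrigin    = list(b = 5.12, f = function(z) {
      sum(z^2 - 10 * cos(2 * pi * z) + 10)
    }),
    ackley       = list(b = 32, f = function(z) {
      d <- length(z)
      -20 * exp(-0.2 * sqrt(sum(z^2) / d)) - exp(sum(cos(2 * pi * z)) / d) +
        20 + exp(1)
    }),
    griewank     = list(b = 600, f = function(z) {
      sum(z^2) / 4000 - prod(cos(z / sqrt(seq_along(z)))) + 1
    }),
    zakharov     = list(b = 10, f = function(z) {
      s <- sum(0.5 * seq_along(z) * z)
      sum(z^2) + s^2 + s^4
    }),
    levy         = list(b = 10, f = function(z) {
      w <- 1 + z / 4
      d <- length(w)
      sin(pi * w[1])^2 +
        sum((w[-d] - 1)^2 * (1 + 10 * sin(pi * w[-d] + 1)^2)) +
        (w[d] - 1)^2 * (1 + sin(2 * pi * w[d])^2)
    }),
    schwefel222  = list(b = 10, f = function(z) sum(abs(z)) + prod(abs(z))),
    alpine       = list(b = 10, f = function(z) {
      sum(abs(z * sin(z) + 0.1 * z))
    }),
    sumpow       = list(b = 1, f = function(z) {
      sum(abs(z)^(seq_along(z) + 1))
    }),
    schaffer_exp = list(b = 100, f = function(z) {
      zz <- c(z, z[1])
      x <- zz[-length(zz)]; y <- zz[-1]
      s <- x^2 + y^2
      sum(0.5 + (sin(sqrt(s))^2 - 0.5) / (1 + 0.001 * s)^2)
    })
  )
  with_seed(shift_seed, {
    out <- lapply(names(defs), function(nm) {
      b <- defs[[nm]]$b
      f0 <- defs[[nm]]$f
      shift <- stats::runif(dim, -0.5 * b, 0.5 * b)
      list(name = nm,
           fn = local({
             f0 <- f0; shift <- shift
             function(x) f0(x - shift)
           }),
           lower = rep(-b, dim), upper = rep(b, dim),
           optimum = shift, f_min = 0)
    })
    names(out) <- names(defs)
    out
  })
}

#' Run the optimizer benchmark protocol
#'
#' For every (function, algorithm) cell, performs `runs` independent
#' seeded runs and records the final best fitness and the convergence
#' trace. The study protocol is dimension 10, population 30, 500
#' iterations and 30 runs; tests use a scaled-down budget.
#'
#' @param algorithms character vector of algorithm names
#'   (see [baseline_optimize()]).
#' @param dim problem dimension.
#' @param pop population size.
#' @param iters iterations per run.
#' @param runs independent runs per cell.
#' @param seed master seed; each run uses an independently derived seed.
#' @param functions optional list from [benchmark_functions()].
#' @return object of class `benchmark_report`: `results` (long data.frame
#'   of final fitness per run), `summary` (min/median/mean/sd per cell) and
#'   `traces` (best-so-far matrices).
#' @export
run_benchmark <- function(algorithms = c("ISequoiaOA", "SequoiaOA"),
                          dim = 10L, pop = 30L, iters = 500L, runs = 30L,
                          seed = 1L, functions = NULL) {
  if (is.null(functions)) {
    functions <- benchmark_functions(dim, shift_seed = derive_seed(seed, 0))
  }
  stopifnot(length(functions) > 0)
  rows <- list(); traces <- list()
  cell <- 0L
  for (fname in names(functions)) {
    fb <- functions[[fname]]
    space <- search_space(fb$lower, fb$upper, dim = length(fb$lower))
    for (alg in algorithms) {
      cell <- cell + 1L
      tr <- matrix(NA_real_, iters, runs)
      for (r in seq_len(runs)) {
        cfg <- optimizer_config(pop_size = pop, max_iters = iters,
                                seed = derive_seed(seed, cell * 1000L + r))
        res <- baseline_optimize(alg, fb$fn, space, cfg)
        tr[, r] <- res$history
        rows[[length(rows) + 1L]] <- data.frame(
          fn = fname, algorithm = alg, run = r,
          final_fitness = res$best_fitness)
      }
      traces[[paste(fname, alg, sep = ".")]] <- tr
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, list(results$fn, results$algorithm)),
    function(d) data.frame(fn = d$fn[1], algorithm = d$algorithm[1],
                           min = min(d$final_fitness),
                           median = stats::median(d$final_fitness),
                           mean = mean(d$final_fitness),
                           sd = stats::sd(d$final_fitness))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, traces = traces,
                 protocol = list(dim = dim, pop = pop, iters = iters,
                                 runs = runs, seed = seed)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d functions x %d algorithms, %d runs each\n",
              length(unique(x$results$fn)),
              length(unique(x$results$algorithm)), x$protocol$runs))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Count functions on which one algorithm beats another by median
#'
#' @param report a `benchmark_report`.
#' @param a,b algorithm names; counts functions where the median final
#'   fitness of `a` is less than or equal to `b`'s.
#' @return integer count of functions where `a`'s median <= `b`'s.
#' @export
median_wins <- function(report, a = "ISequoiaOA", b = "SequoiaOA") {
  s <- report$summary
  fns <- unique(s$fn)
  sum(vapply(fns, function(f) {
    ma <- s$median[s$fn == f & s$algorithm == a]
    mb <- s$median[s$fn == f & s$algorithm == b]
    ma <= mb
  }, logical(1)))
}
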