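# Powell's direction-set minimization (no gradients). Each iteration performs
# a line minimization along every direction, then possibly replaces the
# direction of largest decrease by the net displacement direction (classic
# squared-term acceptance test). Line minimizations bracket the minimum by
# geometric expansion and polish it with Brent's method (stats::optimize).
# Fully deterministic for identical inputs.

line_minimize <- function(f, x, d, f0, xtol, counter) {
  g <- function(t) {
    counter$n <- counter$n + 1L
    v <- f(x + t * d)
    if (!is.finite(v))
      pct_error("non-finite objective during line search",
                "pct_nonfinite_objective_error",
                parameters = x + t * d)
    v
  }
  # bracket a minimum around t = 0
  t1 <- 1
  f1 <- g(t1)
  if (f1 > f0) { t1 <- -1; f1 <- g(t1) }
  if (f1 > f0) {
    # minimum between -1 and 1
    lo <- -1; hi <- 1
  } else {
    t0 <- 0; t2 <- t1 * 2
    f2 <- g(t2)
    nexp <- 0L
    while (f2 < f1 && nexp < 40L) {
      t0 <- t1; t1 <- t2; f1 <- f2
      t2 <- t2 * 2
      f2 <- g(t2)
      nexp <- nexp + 1L
    }
    lo <- min(t0, t2); hi <- max(t0, t2)
  }
  scale_d <- max(abs(d))
  tol_t <- max(xtol / max(scale_d, 1e-12), 1e-10)
  opt <- stats::optimize(g, c(lo, hi), tol = tol_t)
  # keep the incumbent if Brent's interior probe did not beat it
  if (opt$objective <= f0) {
    list(x = x + opt$minimum * d, f = opt$objective)
  } else {
    list(x = x, f = f0)
  }
}

#' Minimize a function with Powell's direction-set method
#'
#' Derivative-free minimization by successive line searches along an evolving
#' direction set, as used for every stage of the registration cascade.
#' Deterministic given identical inputs.
#'
#' @param objective Function of a numeric parameter vector returning a scalar.
#' @param x0 Initial parameter vector (objective must be finite there).
#' @param bounds `NULL` or list with `lower`/`upper` vectors; parameters are
#'   clamped into the box before each evaluation.
#' @param xtol Parameter-space convergence tolerance.
#' @param ftol Relative function-decrease convergence tolerance.
#' @param max_iter Maximum number of full direction-set sweeps.
#' @return List with `par`, `value`, `n_eval`, `n_iter`, `converged`.
#' @export
powell_minimize <- function(objective, x0, bounds = NULL,
                            xtol = 1e-3, ftol = 1e-5, max_iter = 20L) {
  n <- length(x0)
  clamp <- if (is.null(bounds)) identity else function(x)
    pmin(pmax(x, bounds$lower), bounds$upper)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  f <- function(x) objective(clamp(x))
  x <- as.numeric(x0)
  fx <- f(x)
  counter$n <- counter$n + 1L
  if (!is.finite(fx))
    pct_error("objective not finite at the initial point",
              "pct_nonfinite_objective_error", parameters = x)
  dirs <- diag(n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f_start <- fx
    x_start <- x
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      res <- line_minimize(f, x, dirs[, i], fx, xtol, counter)
      dec <- fx - res$f
      if (dec > biggest) { biggest <- dec; ibig <- i }
      x <- res$x
      fx <- res$f
    }
    if (2 * (f_start - fx) <= ftol * (abs(f_start) + abs(fx)) + 1e-25) {
      converged <- TRUE
      break
    }
    # direction replacement (Powell/Numerical-Recipes acceptance test)
    xe <- 2 * x - x_start
    fe <- f(clamp(xe))
    counter$n <- counter$n + 1L
    if (fe < f_start) {
      tst <- 2 * (f_start - 2 * fx + fe) * (f_start - fx - biggest)^2 -
        biggest * (f_start - fe)^2
      if (tst < 0) {
        newdir <- x - x_start
        if (max(abs(newdir)) > 0) {
          res <- line_minimize(f, x, newdir, fx, xtol, counter)
          x <- res$x
          fx <- res$f
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- newdir
        }
      }
    }
    if (max(abs(x - x_start)) <= xtol) {
      converged <- TRUE
      break
    }
  }
  list(par = clamp(x), value = fx, n_eval = counter$n,
       n_iter = iter, converged = converged)
}
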