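# Fitness (missingness) functions and Bayesian mean fitness.
#
# A fitness function H(y | phi) gives the probability, up to scale, that an
# individual with phenotype(s) y survives selection, i.e. that its records
# are observed. Multiplying the likelihood by H and renormalizing yields the
# post-selection model.

#' Selection rule (fitness specification)
#'
#' @param kind `"truncation_above"` (survive iff y > t, strict),
#'   `"truncation_below"` (survive iff y < t, strict), `"nor_optimal"`
#'   (Gaussian stabilizing fitness `exp(-(y-lambda)' Gamma^-1 (y-lambda)/2)`)
#'   or `"constant"` (no selection).
#' @param t threshold(s), trait units, for the truncation kinds; may be
#'   `-Inf`/`Inf`.
#' @param lambda optimum vector for `nor_optimal` (trait units).
#' @param Gamma sharpness matrix (trait units squared) for `nor_optimal`;
#'   a scalar is interpreted as a 1x1 matrix. `Inf` is an explicit
#'   no-selection sentinel (fitness identically 1).
#' @return object of class `fitness_spec`.
#' @export
fitness_spec <- function(kind = c("truncation_above", "truncation_below",
                                  "nor_optimal", "constant"),
                         t = NULL, lambda = NULL, Gamma = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("truncation_above", "truncation_below")) {
    if (is.null(t) || any(is.na(t))) stopf("truncation kinds need threshold t")
  }
  if (kind == "nor_optimal") {
    if (is.null(lambda) || is.null(Gamma)) stopf("nor_optimal needs lambda and Gamma")
    lambda <- as.numeric(lambda)
    if (length(Gamma) == 1 && !is.matrix(Gamma)) Gamma <- matrix(Gamma, 1, 1)
    if (!all(is.infinite(Gamma))) {
      if (!is_symmetric(Gamma)) stopf("Gamma must be symmetric")
      ev <- eigen((Gamma + t(Gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) stopf("Gamma must be positive definite")
    }
    if (nrow(Gamma) != length(lambda)) stopf("lambda and Gamma dimensions differ")
  }
  structure(list(kind = kind, t = t, lambda = lambda, Gamma = Gamma),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  desc <- switch(x$kind,
    truncation_above = sprintf("truncation above t = %s", paste(signif(x$t, 4), collapse = ", ")),
    truncation_below = sprintf("truncation below t = %s", paste(signif(x$t, 4), collapse = ", ")),
    nor_optimal = sprintf("nor-optimal, optimum lambda = (%s)", paste(signif(x$lambda, 4), collapse = ", ")),
    constant = "constant (no selection)")
  cat(sprintf("<fitness_spec: %s>\n", desc))
  invisible(x)
}

#' Evaluate a fitness function at a phenotype
#'
#' Truncation uses strict inequalities (the survival region is an open
#' interval); the boundary has probability zero for continuous traits but the
#' convention is fixed for reproducibility. The nor-optimal fitness peaks at 1
#' when `y = lambda` and tends to 1 everywhere as `Gamma` grows.
#'
#' @param spec a [fitness_spec()].
#' @param y phenotype vector, dimension matching the spec.
#' @return a value in `[0, 1]`.
#' @export
evaluate_fitness <- function(spec, y) {
  stopifnot(inherits(spec, "fitness_spec"))
  y <- as.numeric(y)
  switch(spec$kind,
    constant = 1,
    truncation_above = {
      if (length(y) != length(spec$t) && length(spec$t) != 1)
        stopf("dimension mismatch between y and thresholds")
      as.numeric(all(y > spec$t))
    },
    truncation_below = {
      if (length(y) != length(spec$t) && length(spec$t) != 1)
        stopf("dimension mismatch between y and thresholds")
      as.numeric(all(y < spec$t))
    },
    nor_optimal = {
      if (length(y) != length(spec$lambda)) stopf("dimension mismatch between y and lambda")
      if (all(is.infinite(spec$Gamma))) return(1)
      d <- y - spec$lambda
      exp(-0.5 * drop(crossprod(d, solve(spec$Gamma, d))))
    })
}

#' Bayesian mean fitness under a data-generating density
#'
#' Numerically integrates fitness times density on a grid. For truncation
#' selection on a normal density this is the corresponding tail probability.
#'
#' @param spec a scalar [fitness_spec()].
#' @param grid strictly increasing evaluation points.
#' @param density data-generating density values on `grid`; must integrate to
#'   1 within 1e-6.
#' @return mean fitness in (0, 1].
#' @export
mean_fitness <- function(spec, grid, density) {
  if (abs(trapz(grid, density) - 1) > 1e-6) stopf("density must integrate to 1")
  h <- vapply(grid, function(v) evaluate_fitness(spec, v), numeric(1))
  H <- trapz(grid, h * density)
  if (H <= 1e-12) stopf("degenerate selection: mean fitness is zero")
  min(H, 1)
}

#' Scalar-parameter posterior problem on a grid
#'
#' Bundles log-likelihood, log-prior and a log fitness correction, each a
#' function of the scalar parameter, with the grid they are to be evaluated
#' on. The correction is the log of the selection term that multiplies the
#' no-selection posterior; set it to the zero function for no selection.
#'
#' @param param_name name of the scalar parameter (for printing).
#' @param grid strictly increasing parameter values, length >= 101.
#' @param log_lik,log_prior,log_fitness vectorized functions of the parameter.
#' @return object of class `grid_posterior_problem`.
#' @export
grid_posterior_problem <- function(param_name, grid, log_lik,
                                   log_prior = function(x) rep(0, length(x)),
                                   log_fitness = function(x) rep(0, length(x))) {
  grid <- as.numeric(grid)
  if (length(grid) < 101) stopf("grid must have at least 101 points")
  if (any(diff(grid) <= 0)) stopf("grid must be strictly increasing")
  structure(list(param_name = param_name, grid = grid, log_lik = log_lik,
                 log_prior = log_prior, log_fitness = log_fitness),
            class = "grid_posterior_problem")
}

# Build a normalized posterior_grid object from unnormalized log-density
# values. All normalization happens in log space (log-sum-exp) before the
# trapezoid rule fixes the continuous scale.
new_posterior_grid <- function(grid, log_unnorm, param_name = "theta") {
  if (all(!is.finite(log_unnorm))) stopf("posterior has no support on grid")
  if (any(is.nan(log_unnorm))) stopf("log-density evaluated to NaN")
  lw <- log_unnorm - logsumexp(log_unnorm)
  w <- exp(lw)
  Z <- trapz(grid, w)
  density <- w / Z
  m <- trapz(grid, grid * density)
  v <- trapz(grid, (grid - m)^2 * density)
  structure(list(grid = grid, density = density, mean = m,
                 sd = sqrt(max(v, 0)), mode = grid[which.max(density)],
                 param_name = param_name),
            class = "posterior_grid")
}

#' Posterior density under selection on a grid
#'
#' Computes `density proportional to exp(log_lik + log_prior + log_fitness)`
#' on the problem's grid, normalized by log-sum-exp and the trapezoid rule.
#' With a zero correction this is the ordinary no-selection posterior; adding
#' any constant to any log term leaves the result unchanged.
#'
#' @param problem a [grid_posterior_problem()].
#' @return object of class `posterior_grid` with elements `grid`, `density`,
#'   `mean`, `sd`, `mode`.
#' @export
posterior_under_selection <- function(problem) {
  stopifnot(inherits(problem, "grid_posterior_problem"))
  g <- problem$grid
  lt <- problem$log_lik(g) + problem$log_prior(g) + problem$log_fitness(g)
  new_posterior_grid(g, lt, problem$param_name)
}

#' Equal-tail credible interval from a grid posterior
#'
#' @param pg a `posterior_grid`.
#' @param level interval mass (default 0.95).
#' @return length-2 vector (lower, upper) from the inverse of the trapezoid
#'   CDF.
#' @export
credible_interval <- function(pg, level = 0.95) {
  stopifnot(inherits(pg, "posterior_grid"))
  x <- pg$grid; f <- pg$density
  cdf <- c(0, cumsum((x[-1] - x[-length(x)]) * (f[-1] + f[-length(x)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  a <- (1 - level) / 2
  qf <- function(p) {
    i <- findInterval(p, cdf, all.inside = TRUE)
    # linear interpolation inside the bracketing cell
    d <- cdf[i + 1] - cdf[i]
    if (d <= 0) return(x[i])
    x[i] + (p - cdf[i]) / d * (x[i + 1] - x[i])
  }
  c(qf(a), qf(1 - a))
}

#' @export
print.posterior_grid <- function(x, ...) {
  ci <- credible_interval(x)
  cat(sprintf("<posterior_grid for %s: mean %.4f, sd %.4f, mode %.4f, 95%% CI [%.4f, %.4f]>\n",
              x$param_name, x$mean, x$sd, x$mode, ci[1], ci[2]))
  invisible(x)
}

#' @export
summary.posterior_grid <- function(object, level = 0.95, ...) {
  ci <- credible_interval(object, level)
  c(mean = object$mean, sd = object$sd, mode = object$mode,
    lower = ci[1], upper = ci[2])
}

#' @export
plot.posterior_grid <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", xlab = x$param_name,
                 ylab = "posterior density", ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}

#' Numeric ignorability check
#'
#' Sup-norm distance between two normalized grid posteriors with identical
#' grids; near zero when the selection process is ignorable (fitness depends
#' on observed data only, with selection parameters a priori independent of
#' the model parameters).
#'
#' @param problem_with_fitness,problem_without_fitness two
#'   [grid_posterior_problem()]s on the same grid.
#' @return maximum absolute density difference.
#' @export
check_ignorability <- function(problem_with_fitness, problem_without_fitness) {
  g1 <- problem_with_fitness$grid; g2 <- problem_without_fitness$grid
  if (length(g1) != length(g2) || any(g1 != g2)) stopf("grids must be identical")
  p1 <- posterior_under_selection(problem_with_fitness)
  p2 <- posterior_under_selection(problem_without_fitness)
  max(abs(p1$density - p2$density))
}

#' Serialize a fitness specification to JSON or YAML
#'
#' @param spec a [fitness_spec()].
#' @param path output file; format chosen by extension (`.json`, `.yml`,
#'   `.yaml`).
#' @export
write_fitness_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fitness_spec"))
  obj <- list(kind = spec$kind)
  if (!is.null(spec$t)) obj$t <- spec$t
  if (!is.null(spec$lambda)) obj$lambda <- spec$lambda
  if (!is.null(spec$Gamma)) obj$Gamma <- as.vector(spec$Gamma)
  if (!is.null(spec$Gamma)) obj$Gamma_dim <- nrow(spec$Gamma)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a fitness specification from JSON or YAML
#'
#' @param path file written by [write_fitness_spec()].
#' @return a [fitness_spec()].
#' @export
read_fitness_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  Gamma <- NULL
  if (!is.null(obj$Gamma)) Gamma <- matrix(unlist(obj$Gamma), obj$Gamma_dim, obj$Gamma_dim)
  fitness_spec(kind = obj$kind, t = obj$t,
               lambda = if (is.null(obj$lambda)) NULL else unlist(obj$lambda),
               Gamma = Gamma)
}
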