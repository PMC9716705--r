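# MCMC chain container and convergence diagnostics.

#' MCMC chain
#'
#' @param draws iterations x dimensions matrix of sampled values.
#' @param acceptance_rate fraction of proposals accepted.
#' @param seed seed(s) used.
#' @param log notes recorded during sampling (acceptance per block etc.).
#' @return object of class `mcmc_chain`.
#' @export
mcmc_chain <- function(draws, acceptance_rate, seed = NA_integer_, log = NULL) {
  draws <- as.matrix(draws)
  if (any(!is.finite(draws))) stopf("chain contains non-finite draws")
  if (acceptance_rate < 0 || acceptance_rate > 1) stopf("acceptance rate outside [0,1]")
  structure(list(draws = draws, acceptance_rate = acceptance_rate,
                 seed = seed, log = log),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain: %d iterations x %d dimensions, acceptance %.3f>\n",
              nrow(x$draws), ncol(x$draws), x$acceptance_rate))
  invisible(x)
}

#' @export
plot.mcmc_chain <- function(x, dims = seq_len(min(4, ncol(x$draws))), ...) {
  op <- graphics::par(mfrow = c(length(dims), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (j in dims) {
    graphics::plot(x$draws[, j], type = "l", ylab = paste0("dim ", j), ...)
  }
  invisible(x)
}

#' Split potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting each chain in half, so a
#' single non-stationary chain is flagged too.
#'
#' @param draws a matrix (one chain) or list of equally sized matrices
#'   (several chains), iterations x dimensions.
#' @return vector of R-hat values, one per dimension.
#' @export
split_rhat <- function(draws) {
  if (is.matrix(draws)) draws <- list(draws)
  halves <- list()
  for (d in draws) {
    n <- nrow(d); h <- floor(n / 2)
    halves <- c(halves, list(d[1:h, , drop = FALSE], d[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]]); p <- ncol(halves[[1]])
  vapply(seq_len(p), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(n))  # n x m
    mu <- colMeans(x)
    B <- n * stats::var(mu)
    W <- mean(apply(x, 2, stats::var))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Effective sample size
#'
#' Initial-positive-sequence estimator from the empirical autocorrelation
#' function, per dimension.
#'
#' @param draws iterations x dimensions matrix.
#' @return vector of ESS values.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  vapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(ac)) {
      if (ac[k] < 0.0) break
      s <- s + ac[k]
    }
    max(1, n / (1 + 2 * s))
  }, numeric(1))
}

#' Posterior summaries of an MCMC chain
#'
#' Per-dimension posterior mean, sd, 95% equal-tail interval from empirical
#' quantiles, split R-hat and effective sample size, computed on the
#' post-burn-in draws.
#'
#' @param chain an [mcmc_chain()].
#' @param burn_in number of initial iterations to discard (must be smaller
#'   than the number of iterations; default 20% of them).
#' @param level credible level (default 0.95).
#' @return data frame, one row per dimension.
#' @export
summarize_chain <- function(chain, burn_in = floor(0.2 * nrow(chain$draws)),
                            level = 0.95) {
  stopifnot(inherits(chain, "mcmc_chain"))
  n <- nrow(chain$draws)
  if (burn_in >= n) stopf("burn_in (%d) must be smaller than iterations (%d)", burn_in, n)
  d <- chain$draws[(burn_in + 1):n, , drop = FALSE]
  a <- (1 - level) / 2
  q <- t(apply(d, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  data.frame(dim = seq_len(ncol(d)),
             mean = colMeans(d),
             sd = apply(d, 2, stats::sd),
             lower = q[, 1], upper = q[, 2],
             rhat = split_rhat(d),
             ess = ess_basic(d))
}
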