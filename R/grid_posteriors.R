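# Scalar-parameter selection-corrected posteriors:
#   - two-country truncation on a correlated trait (records used for
#     selection never observed),
#   - truncation posterior when all retained records exceed a threshold,
#   - the nor-optimal (stabilizing-selection) posterior of a population mean.

#' Parameters of the correlated-trait truncation setting
#'
#' Performances in two populations ("country A", where truncation selection
#' at threshold `t` operates, and "country B", where records are collected)
#' are a bivariate normal per individual. Only trait-B records of individuals
#' whose trait-A value exceeded `t` reach the analyst.
#'
#' @param mu_A known mean of the selection trait.
#' @param sigma_A,sigma_B trait standard deviations (> 0).
#' @param rho correlation between the two traits, |rho| < 1.
#' @param t truncation threshold applied to trait A.
#' @return object of class `bivariate_trait_params`.
#' @export
bivariate_trait_params <- function(mu_A = 0, sigma_A = 1, sigma_B = 1, rho, t) {
  if (!(sigma_A > 0) || !(sigma_B > 0)) stopf("sds must be > 0")
  if (abs(rho) >= 1) stopf("|rho| must be < 1")
  structure(list(mu_A = mu_A, sigma_A = sigma_A, sigma_B = sigma_B,
                 rho = rho, t = t),
            class = "bivariate_trait_params")
}

#' Log fitness correction for the correlated-trait truncation posterior
#'
#' For candidate mean `mu_B` the correction is
#' `sum_i log[1 - Phi((t - mu_A.B_i) / sqrt(v_A.B))]` with
#' `mu_A.B_i = mu_A + b (y_iB - mu_B)`, `b = rho sigma_A / sigma_B` and
#' `v_A.B = sigma_A^2 (1 - rho^2)`: the log-probability that each observed
#' individual's (unobserved) selection-trait record exceeded the threshold,
#' given its observed record. Vectorized over `mu_B`.
#'
#' @param mu_B candidate value(s) of the unknown mean of the observed trait.
#' @param y_B_obs observed trait-B records of the selected individuals.
#' @param params a [bivariate_trait_params()].
#' @return numeric vector, one correction per element of `mu_B`.
#' @export
example1_log_correction <- function(mu_B, y_B_obs, params) {
  stopifnot(inherits(params, "bivariate_trait_params"))
  b <- params$rho * params$sigma_A / params$sigma_B
  v <- params$sigma_A^2 * (1 - params$rho^2)
  if (params$t == -Inf) return(rep(0, length(mu_B)))
  # rows: observations, cols: candidate mu_B values
  muAB <- outer(y_B_obs, mu_B, function(y, m) params$mu_A + b * (y - m))
  colSums(log1mPhi((params$t - muAB) / sqrt(v)))
}

# widen a grid until the posterior edges are numerically negligible
adaptive_grid_posterior <- function(center, halfwidth, log_unnorm_fun, param_name,
                                    n_grid = 2001, max_doublings = 8) {
  for (k in 0:max_doublings) {
    g <- seq(center - halfwidth, center + halfwidth, length.out = n_grid)
    lt <- log_unnorm_fun(g)
    pg <- new_posterior_grid(g, lt, param_name)
    edge <- max(pg$density[1], pg$density[n_grid])
    if (edge < 1e-12 * max(pg$density)) return(pg)
    halfwidth <- 2 * halfwidth
  }
  pg
}

#' Posterior of the observed-trait mean under correlated-trait truncation
#'
#' The selection-corrected posterior multiplies the Gaussian kernel
#' `exp(-sum_i (y_iB - mu_B)^2 / (2 sigma_B^2))` (flat prior) by the
#' exponentiated [example1_log_correction()]. The selection-ignoring
#' posterior `N(mean(y_B), sigma_B^2/m)` is returned alongside for
#' comparison. The grid starts at the selection-ignoring mean +/- 8 of its
#' posterior sds and is widened adaptively until the corrected mass is
#' contained, since truncation can displace the posterior far below the
#' naive mean.
#'
#' @param y_B_obs observed trait-B records (length m >= 1).
#' @param params a [bivariate_trait_params()].
#' @param n_grid number of grid points (default 2001).
#' @return list with elements `corrected` and `ignoring`, both
#'   `posterior_grid` objects on the same grid.
#' @export
example1_posterior <- function(y_B_obs, params, n_grid = 2001) {
  if (length(y_B_obs) < 1) stopf("no observed records")
  m <- length(y_B_obs)
  ybar <- mean(y_B_obs)
  sd0 <- params$sigma_B / sqrt(m)
  log_kernel <- function(mu) -m * (mu - ybar)^2 / (2 * params$sigma_B^2)
  corrected <- adaptive_grid_posterior(
    ybar, 8 * sd0,
    function(mu) log_kernel(mu) + example1_log_correction(mu, y_B_obs, params),
    "mu_B", n_grid)
  ignoring <- new_posterior_grid(corrected$grid, log_kernel(corrected$grid), "mu_B")
  list(corrected = corrected, ignoring = ignoring)
}

#' Truncation posterior when all retained records exceed a threshold
#'
#' Every record presented to the analyst is known to exceed `t`; the
#' likelihood is a product of truncated normal densities and, under a flat
#' prior, the posterior of the mean is proportional to
#' `exp(-n (mu - ybar)^2 / (2 sigma^2)) / [1 - Phi((t - mu)/sigma)]^n`.
#'
#' @param y records, all strictly greater than `t`.
#' @param t known truncation threshold.
#' @param sigma2 known variance.
#' @param n_grid grid size (default 2001).
#' @return a `posterior_grid` for the pre-selection mean.
#' @export
harville_truncation_posterior <- function(y, t, sigma2, n_grid = 2001) {
  if (any(y <= t)) stopf("data inconsistent with truncation: some y <= t")
  n <- length(y); ybar <- mean(y); sigma <- sqrt(sigma2)
  lfun <- function(mu) {
    -n * (mu - ybar)^2 / (2 * sigma2) - n * log1mPhi((t - mu) / sigma)
  }
  adaptive_grid_posterior(ybar, 8 * sigma / sqrt(n), lfun, "mu", n_grid)
}

#' Posterior of the base-population mean under nor-optimal selection
#'
#' The analyst observes `m` phenotypes from a population that underwent one
#' round of stabilizing selection towards optimum `lambda` with centripetal
#' coefficient `S`; post-selection phenotypes are `N(mu(1-S) + lambda S,
#' 1-S)` for pre-selection mean `mu` (unit pre-selection variance). Under a
#' flat prior the posterior of `mu` is normal with mean
#' `(ybar - lambda S)/(1 - S)` and variance `1/(m (1 - S))` (the observed
#' sample size is used in the variance).
#'
#' @param y_bar observed post-selection sample mean.
#' @param m observed sample size.
#' @param lambda_opt selection optimum.
#' @param S centripetal coefficient in `[0, 1)`.
#' @return list with `mean` and `variance` of the normal posterior.
#' @export
nor_optimal_mu_posterior <- function(y_bar, m, lambda_opt, S) {
  if (S < 0 || S >= 1) stopf("S must be in [0, 1)")
  if (m < 1) stopf("m must be >= 1")
  list(mean = (y_bar - lambda_opt * S) / (1 - S),
       variance = 1 / (m * (1 - S)))
}
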