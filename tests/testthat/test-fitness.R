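test_that("fitness functions evaluate their defining forms", {
  # stabilizing fitness peaks at 1 on the optimum and relaxes as gamma grows
  ns <- fitness_spec("nor_optimal", lambda = c(1, -1), Gamma = diag(2))
  expect_equal(evaluate_fitness(ns, c(1, -1)), 1)
  soft <- fitness_spec("nor_optimal", lambda = 0, Gamma = matrix(1e12))
  expect_gt(evaluate_fitness(soft, 5), 1 - 1e-6)
  g1 <- fitness_spec("nor_optimal", lambda = 2, Gamma = matrix(4))
  expect_equal(evaluate_fitness(g1, 2 + 2), exp(-1 / 2), tolerance = 1e-12)

  tr <- fitness_spec("truncation_above", t = 0)
  expect_identical(evaluate_fitness(tr, 0), 0)   # strict inequality at the boundary
  expect_identical(evaluate_fitness(tr, 1e-12), 1)
  expect_identical(evaluate_fitness(fitness_spec("constant"), 3), 1)
  expect_error(evaluate_fitness(ns, 1), "dimension mismatch")
  expect_error(fitness_spec("nor_optimal", lambda = 0, Gamma = matrix(-1)), "positive definite")
})

test_that("mean fitness integrates fitness against the data density", {
  grid <- seq(-8, 8, length.out = 4001)
  dens <- dnorm(grid)
  # trapezoid error at the indicator jump is O(grid step)
  expect_lt(abs(mean_fitness(fitness_spec("truncation_below", t = 0), grid, dens) - 0.5),
            2e-3)
  # normal tail checked against an independent CDF implementation
  tail1 <- 1 - Phi_num(1)
  expect_lt(abs(mean_fitness(fitness_spec("truncation_above", t = 1), grid, dens) - tail1),
            2e-3)
  expect_equal(mean_fitness(fitness_spec("constant"), grid, dens), 1, tolerance = 1e-6)
  expect_error(mean_fitness(fitness_spec("truncation_above", t = 20), grid, dens),
               "degenerate selection")
  expect_error(mean_fitness(fitness_spec("constant"), grid, 2 * dens), "integrate to 1")
})

test_that("grid posterior reproduces the conjugate normal and ignores constants", {
  n <- 25; ybar <- 0.3
  prob <- grid_posterior_problem(
    "mu", seq(ybar - 8 / sqrt(n), ybar + 8 / sqrt(n), length.out = 2001),
    log_lik = function(mu) -n * (mu - ybar)^2 / 2)
  pg <- posterior_under_selection(prob)
  expect_equal(pg$mean, ybar, tolerance = 1e-3)
  expect_equal(pg$sd, 1 / sqrt(n), tolerance = 1e-3)
  expect_equal(trapz(pg$grid, pg$density), 1, tolerance = 1e-6)
  ci <- credible_interval(pg)
  expect_equal(ci, ybar + qnorm(c(0.025, 0.975)) / sqrt(n), tolerance = 1e-3)

  # a correction constant in the parameter cancels in the normalization
  prob2 <- grid_posterior_problem("mu", prob$grid,
    log_lik = function(mu) -n * (mu - ybar)^2 / 2 + 7,
    log_prior = function(mu) rep(-3, length(mu)),
    log_fitness = function(mu) rep(-123.4, length(mu)))
  pg2 <- posterior_under_selection(prob2)
  expect_equal(pg2$density, pg$density, tolerance = 1e-12)

  allneg <- grid_posterior_problem("mu", prob$grid,
    log_lik = function(mu) rep(-Inf, length(mu)))
  expect_error(posterior_under_selection(allneg), "no support")
})

test_that("ignorability holds iff the correction varies with the parameter", {
  sim <- simulate_bivariate_selection(400, 0.8, threshold = 0, seed = 31)
  yB <- sim$y_B_obs; m <- length(yB)
  grid <- seq(mean(yB) - 3, mean(yB) + 1, length.out = 2001)
  loglik <- function(mu) -m * (mu - mean(yB))^2 / 2
  base <- grid_posterior_problem("mu_B", grid, loglik)

  # fitness of the observed data only, fixed selection parameter: a constant
  const <- sum(log(0.4))
  obs_only <- grid_posterior_problem("mu_B", grid, loglik,
    log_fitness = function(mu) rep(const, length(mu)))
  expect_lt(check_ignorability(obs_only, base), 1e-10)

  # uncorrelated traits: correction does not involve the mean
  p0 <- bivariate_trait_params(rho = 0, t = 0)
  rho0 <- grid_posterior_problem("mu_B", grid, loglik,
    log_fitness = function(mu) example1_log_correction(mu, yB, p0))
  expect_lt(check_ignorability(rho0, base), 1e-10)

  # correlated traits: the correction moves the posterior
  p8 <- bivariate_trait_params(rho = 0.8, t = 0)
  rho8 <- grid_posterior_problem("mu_B", grid, loglik,
    log_fitness = function(mu) example1_log_correction(mu, yB, p8))
  expect_gt(check_ignorability(rho8, base), 0.1)

  expect_error(check_ignorability(base,
    grid_posterior_problem("mu_B", grid + 1, loglik)), "identical")
})

test_that("observed-data selection leaves predictive and model probabilities unchanged", {
  set.seed(5)
  y <- rnorm(12, 0.4)
  n <- length(y); ybar <- mean(y)
  grid <- seq(ybar - 6 / sqrt(n), ybar + 6 / sqrt(n), length.out = 2001)
  loglik <- function(mu) -n * (mu - ybar)^2 / 2
  # two nested models: flat prior vs N(0,1) prior on the mean
  priors <- list(function(mu) rep(0, length(mu)), function(mu) dnorm(mu, log = TRUE))
  # an observed-data-only fitness factor with fixed phi: constant in mu
  hconst <- sum(log(punif(y, -5, 5)))
  marg <- function(lp, lf) {
    prob <- grid_posterior_problem("mu", grid, loglik, lp, lf)
    lt <- loglik(grid) + lp(grid) + lf(grid)
    log(trapz(grid, exp(lt - max(lt)))) + max(lt)
  }
  zero <- function(mu) rep(0, length(mu))
  hfun <- function(mu) rep(hconst, length(mu))
  m_nosel <- vapply(priors, function(p) marg(p, zero), numeric(1))
  m_sel <- vapply(priors, function(p) marg(p, hfun), numeric(1))
  pm_nosel <- exp(m_nosel) / sum(exp(m_nosel))
  pm_sel <- exp(m_sel) / sum(exp(m_sel))
  expect_lt(max(abs(pm_sel - pm_nosel) / pm_nosel), 1e-8)

  # posterior-predictive density of a future record on a grid
  yf <- seq(-3, 4, length.out = 301)
  predictive <- function(lf) {
    pg <- posterior_under_selection(grid_posterior_problem("mu", grid, loglik, priors[[2]], lf))
    vapply(yf, function(v) trapz(grid, dnorm(v, pg$grid, 1) * pg$density), numeric(1))
  }
  expect_lt(max(abs(predictive(hfun) - predictive(zero))), 1e-8)
})

test_that("fitness specs round-trip through JSON and YAML", {
  sp <- fitness_spec("nor_optimal", lambda = c(0.5, -2), Gamma = matrix(c(2, 0.3, 0.3, 1), 2, 2))
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_fitness_spec(sp, f)
    sp2 <- read_fitness_spec(f)
    expect_equal(sp2$kind, sp$kind)
    expect_equal(sp2$lambda, sp$lambda)
    expect_equal(sp2$Gamma, sp$Gamma)
  }
  f <- tempfile(fileext = ".json")
  write_fitness_spec(fitness_spec("truncation_above", t = 1.5), f)
  expect_equal(read_fitness_spec(f)$t, 1.5)
})
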