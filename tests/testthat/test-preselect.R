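# 3-individual toy with hand-set dispersion quantities
toy_preselect <- function(t = 0.3, rho = 0.75) {
  Gs <- relationship_matrix(matrix(c(1, 0.3, 0.1,
                                     0.3, 1, 0.2,
                                     0.1, 0.2, 1), 3, 3), kind = "genomic")
  As <- relationship_matrix(matrix(c(1, 0.25, 0,
                                     0.25, 1, 0.5,
                                     0, 0.5, 1), 3, 3), kind = "pedigree")
  preselection_model(t = t, rho_ga = rho,
                     sigma2_ahat_i = c(0.2, 0.25, 0.22),
                     sigma2_g_i = c(0.5, 0.5, 0.5),
                     G_sel = Gs, vc_g = variance_components(0.5, 0.5),
                     y_sel = c(0.8, -0.2, 0.5),
                     A_sel = As, vc_a = variance_components(0.4, 0.6))
}

test_that("selection-ignoring genomic posterior of survivors matches BLUP algebra", {
  mod <- toy_preselect()
  gb <- gblup_sel(mod)
  G <- mod$G_sel$K * 0.5; R <- diag(0.5, 3)
  expect_equal(gb$mean, unname(drop(G %*% solve(G + R, mod$y_sel))), tolerance = 1e-10)

  one <- preselection_model(t = 0, sigma2_ahat_i = 0.2, sigma2_g_i = 0.5,
                            G_sel = matrix(1), vc_g = variance_components(1, 1),
                            y_sel = 2)
  expect_equal(gblup_sel(one)$mean, 1)

  mod0 <- toy_preselect()
  mod0$y_sel <- rep(0, 3)
  expect_equal(gblup_sel(mod0)$mean, rep(0, 3))
})

test_that("pre-selection correction is constant as rho vanishes and monotone in g", {
  mod <- toy_preselect(rho = 1e-9)
  g1 <- c(-1, 0, 1); g2 <- c(2, -3, 0.5)
  d <- abs(preselection_log_posterior(g1, mod) - preselection_log_posterior(g1, mod, correction = FALSE) -
           (preselection_log_posterior(g2, mod) - preselection_log_posterior(g2, mod, correction = FALSE)))
  expect_lt(d, 1e-8)

  # larger genomic value => higher survival probability, coordinate-wise
  mod2 <- toy_preselect()
  base <- c(0.1, -0.4, 0.6)
  for (i in 1:3) {
    lo <- base; hi <- base; hi[i] <- hi[i] + 0.5
    corr <- function(g) preselection_log_posterior(g, mod2) -
      preselection_log_posterior(g, mod2, correction = FALSE)
    expect_gte(corr(hi), corr(lo))
  }

  # validation of the conditional-variance requirement
  expect_error(
    preselection_model(t = 0, sigma2_ahat_i = 0.6, sigma2_g_i = 0.5,
                       G_sel = matrix(1), vc_g = variance_components(1, 1), y_sel = 1),
    "sigma2_ahat")
})

test_that("corrected sampler matches lattice and rejection oracles on the toy", {
  mod <- toy_preselect()
  gp <- gblup_sel(mod)
  sds <- sqrt(diag(gp$cov))

  ch <- run_preselection_sampler(mod, 30000, seed = 81)
  post <- ch$draws[-(1:6000), ]

  # rejection oracle from the Gaussian part
  ora <- rejection_oracle(3e5, gp$mean, gp$cov,
                          function(g) selinf:::preselect_correction(g, mod), seed = 82)
  expect_gt(nrow(ora), 3000)
  # two-sample comparison: both sides carry Monte-Carlo noise
  expect_lt(tv_marginals(post, ora), 0.08)

  # lattice normalization of exp(log posterior), marginal by marginal
  grids <- lapply(1:3, function(i) seq(gp$mean[i] - 5 * sds[i], gp$mean[i] + 5 * sds[i],
                                       length.out = 33))
  latt <- as.matrix(expand.grid(grids))
  lp <- apply(latt, 1, function(g) preselection_log_posterior(g, mod))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  for (i in 1:3) {
    marg <- vapply(seq_along(grids[[i]]),
                   function(k) sum(w[latt[, i] == grids[[i]][k]]), numeric(1))
    dens <- marg / diff(grids[[i]][1:2])
    expect_lt(tv_sample_vs_grid(post[, i], grids[[i]], dens), 0.05)
  }
})

test_that("with the correction disabled the chain recovers its Gaussian target", {
  mod <- make_preselect_model(seed = 301)
  gb <- gblup_sel(mod)
  ch <- run_preselection_sampler(mod, 20000, seed = 83, correction = FALSE)
  s <- summarize_chain(ch, burn_in = 4000)
  se <- s$sd / sqrt(s$ess)
  expect_true(all(abs(s$mean - gb$mean) < 3.5 * se))
})

test_that("chains from different seeds converge together", {
  mod <- toy_preselect()
  ch1 <- run_preselection_sampler(mod, 20000, seed = 84)
  ch2 <- run_preselection_sampler(mod, 20000, seed = 85)
  rh <- split_rhat(list(ch1$draws[-(1:4000), ], ch2$draws[-(1:4000), ]))
  expect_true(all(rh < 1.05))
})

test_that("accounting for pre-selection shifts posterior means upward", {
  mod <- make_preselect_model(seed = 302)
  gb <- gblup_sel(mod)
  ch <- run_preselection_sampler(mod, 20000, seed = 86)
  s <- summarize_chain(ch, burn_in = 4000)
  se <- s$sd / sqrt(s$ess)
  expect_true(all(s$mean >= gb$mean - 3 * se))
  # and the shift is real in aggregate
  expect_gt(mean(s$mean - gb$mean), 0)
})

test_that("the verbatim published acceptance ratio is available for replication", {
  mod <- toy_preselect()
  ch <- run_preselection_sampler(mod, 5000, seed = 87, mode = "as_printed")
  expect_gt(ch$acceptance_rate, 0)
  expect_equal(ncol(ch$draws), 3)
})
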