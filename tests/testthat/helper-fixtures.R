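# Shared fixtures and independent oracle helpers.

# Published wheat multi-environment covariance estimates, used as printed
# (including the asymmetric residual cell, which symmetrization resolves).
G0_WHEAT <- matrix(c(
   0.831, -0.319, -0.247, -0.350,
  -0.319,  0.750, -0.195, -0.213,
  -0.247, -0.195,  0.757, -0.176,
  -0.350, -0.213, -0.176,  0.752), 4, 4, byrow = TRUE)

R0_WHEAT <- matrix(c(
   0.830, -0.225, -0.289, -0.202,
  -0.225,  0.872, -0.330, -0.317,
  -0.289, -0.3330, 0.918, -0.352,
  -0.202, -0.317, -0.352,  0.895), 4, 4, byrow = TRUE)

# Published wheat single-trait variance components
VC_WHEAT <- list(sigma2_a = 0.2859, sigma2_e = 0.5761, h2_a = 0.3316,
                 sigma2_g = 0.5315)

# Published sequential culling levels
CULL_T_WHEAT <- c(0, 0.6, 1.3)

# Standard normal CDF by quadrature, independent of pnorm's implementation
Phi_num <- function(z) {
  vapply(z, function(zz) {
    if (zz == -Inf) return(0)
    if (zz == Inf) return(1)
    stats::integrate(stats::dnorm, -Inf, zz, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Maximum, over columns, of the total-variation distance between binned
# empirical distributions of two sample matrices.
tv_marginals <- function(a, b, nbins = 25) {
  a <- as.matrix(a); b <- as.matrix(b)
  max(vapply(seq_len(ncol(a)), function(j) {
    rng <- range(a[, j], b[, j])
    br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nbins + 1)
    pa <- tabulate(findInterval(a[, j], br, all.inside = TRUE), nbins) / nrow(a)
    pb <- tabulate(findInterval(b[, j], br, all.inside = TRUE), nbins) / nrow(b)
    0.5 * sum(abs(pa - pb))
  }, numeric(1)))
}

# Total-variation distance between a sample and a grid density
tv_sample_vs_grid <- function(x, grid, density, nbins = 30) {
  br <- seq(min(grid), max(grid), length.out = nbins + 1)
  px <- tabulate(findInterval(x, br, all.inside = TRUE), nbins) / length(x)
  cdf <- c(0, cumsum(diff(grid) * (density[-1] + density[-length(density)]) / 2))
  pg <- diff(stats::approx(grid, cdf, xout = br, rule = 2)$y)
  pg <- pmax(pg, 0); pg <- pg / sum(pg)
  0.5 * sum(abs(px - pg))
}

# Standard error of a sample covariance entry under normality
cov_entry_se <- function(S, n, i, j) sqrt((S[i, i] * S[j, j] + S[i, j]^2) / n)

# Acceptance-rejection draws from a nor-optimal-selected multivariate normal
ar_nor_optimal <- function(n_prop, m, V, sel_idx, lambda, Gamma, seed) {
  set.seed(seed)
  Y <- MASS::mvrnorm(n_prop, m, V)
  Ginv <- solve(as.matrix(Gamma))
  D <- Y[, sel_idx, drop = FALSE] - matrix(lambda, n_prop, length(sel_idx), byrow = TRUE)
  h <- exp(-0.5 * rowSums((D %*% Ginv) * D))
  Y[stats::runif(n_prop) < h, , drop = FALSE]
}

# small genomic relationship fixture
toy_genomic_K <- function(n, p, seed) {
  pop <- simulate_genomic_population(n, p, sigma2_g = 1, sigma2_e = 1, seed = seed)
  genomic_relationship(pop$X)
}

# bent version: a centered-marker G is always singular (the ones-vector is in
# its null space); blending a little identity in ("bending") keeps toy
# models invertible without changing their character
bent_genomic_K <- function(n, p, seed, w = 0.1) {
  K <- toy_genomic_K(n, p, seed)
  relationship_matrix((1 - w) * K$K + w * diag(n), ids = K$ids, kind = "genomic")
}

# Pre-selection pipeline fixture: pedigree population, pedigree BLUP,
# truncation of the BLUPs at quantile q, genomic data for the survivors.
make_preselect_model <- function(seed, founders = 20, q = 0.7) {
  pop <- simulate_pedigree_population(founders, 2, 2, h2 = 0.4, seed = seed)
  n <- length(pop$y)
  vc_a <- variance_components(0.4, 0.6)
  ab <- blup_posterior(pop$y - mean(pop$y), pop$A, vc_a)
  t <- unname(stats::quantile(ab$mean, q))
  sel <- which(ab$mean > t)
  gp <- simulate_genomic_population(n, 300, sigma2_g = 0.5, sigma2_e = 0.5,
                                   seed = seed + 1)
  G <- genomic_relationship(gp$X)
  vc_g <- variance_components(0.5, 0.5)
  Gs <- relationship_matrix(G$K[sel, sel, drop = FALSE], kind = "genomic")
  preselection_model(
    t = t,
    sigma2_ahat_i = blup_reliability_variance(pop$A, vc_a)[sel],
    sigma2_g_i = diag(Gs$K) * vc_g$sigma2_u,
    G_sel = Gs, vc_g = vc_g,
    y_sel = gp$y[sel] - mean(gp$y),
    A_sel = relationship_matrix(pop$A$K[sel, sel, drop = FALSE], kind = "pedigree"),
    vc_a = vc_a)
}

# Rejection-sampling oracle for a selection-corrected Gaussian: draw from the
# Gaussian part N(mean, cov), accept with probability exp(log_correction),
# which lies in (0, 1] for log-orthant corrections.
rejection_oracle <- function(n_prop, mean, cov, log_correction, seed) {
  set.seed(seed)
  X <- MASS::mvrnorm(n_prop, mean, cov)
  lc <- apply(X, 1, log_correction)
  X[log(stats::runif(n_prop)) < lc, , drop = FALSE]
}
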