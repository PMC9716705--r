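# Lower-orthant multivariate normal probabilities, dimensions 1-3.
#
# The trivariate case is what the sequential-culling fitness needs. The
# bivariate probability uses the exact single-integral identity
#   P(X < h, Y < k; r) = Phi(h) Phi(k)
#     + (1/2pi) Int_0^asin(r) exp(-(h^2 - 2 h k sin t + k^2)/(2 cos^2 t)) dt,
# integrated adaptively; the trivariate case conditions on the first
# coordinate and integrates the conditional bivariate probability. Both are
# deterministic, which matters because Metropolis acceptance ratios must see
# a reproducible target density.

pbvn_std <- function(h, k, r, abs_tol = 1e-10) {
  if (r >= 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (r <= -1 + 1e-12) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (abs(r) < 1e-14) return(base)
  f <- function(t) exp(-(h^2 - 2 * h * k * sin(t) + k^2) / (2 * cos(t)^2))
  corr <- stats::integrate(f, 0, asin(r), abs.tol = abs_tol,
                           rel.tol = 1e-10, subdivisions = 200L)$value
  min(max(base + corr / (2 * pi), 0), 1)
}

ptvn_std <- function(b, R, abs_tol = 1e-7) {
  # condition on x1 < b1; conditional of (x2, x3) given x1 = x is bivariate
  s2 <- sqrt(1 - R[1, 2]^2); s3 <- sqrt(1 - R[1, 3]^2)
  r23 <- (R[2, 3] - R[1, 2] * R[1, 3]) / (s2 * s3)
  r23 <- min(max(r23, -1), 1)
  f <- function(x) {
    vapply(x, function(xx) {
      stats::dnorm(xx) * pbvn_std((b[2] - R[1, 2] * xx) / s2,
                                  (b[3] - R[1, 3] * xx) / s3, r23)
    }, numeric(1))
  }
  v <- stats::integrate(f, -Inf, b[1], abs.tol = abs_tol, rel.tol = 1e-8,
                        subdivisions = 400L)
  min(max(v$value, 0), 1)
}

#' Lower-orthant multivariate normal probability (d <= 3)
#'
#' `Pr(X_1 < upper_1, ..., X_d < upper_d)` for `X ~ N(mean, sigma)`,
#' evaluated deterministically to absolute tolerance about 1e-6 or better.
#'
#' @param upper vector of upper limits (may contain `Inf`).
#' @param mean mean vector (default zero).
#' @param sigma covariance matrix (default identity).
#' @return probability in `[0, 1]`.
#' @export
pmvnorm_lower <- function(upper, mean = rep(0, length(upper)), sigma = diag(length(upper))) {
  d <- length(upper)
  sigma <- as.matrix(sigma)
  if (any(dim(sigma) != d) || length(mean) != d) stopf("dimension mismatch")
  sd <- sqrt(diag(sigma))
  if (any(sd <= 0)) stopf("sigma must have positive diagonal")
  b <- (upper - mean) / sd
  # drop infinite limits: they impose no constraint
  act <- which(is.finite(b))
  if (length(act) == 0) return(1)
  if (any(b[-act] == -Inf)) return(0)
  R <- stats::cov2cor(sigma)[act, act, drop = FALSE]
  b <- b[act]
  switch(as.character(length(b)),
    "1" = stats::pnorm(b),
    "2" = pbvn_std(b[1], b[2], R[1, 2]),
    "3" = ptvn_std(b, R),
    stopf("orthant probabilities implemented for dimension <= 3 (got %d)", length(b)))
}
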