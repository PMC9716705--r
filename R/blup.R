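# Pedigree / genomic BLUP as Gaussian posteriors, single-kernel maximum
# likelihood for variance components, and the sampling moments of BLUP when
# selection modifies the phenotype distribution.

#' BLUP posterior of breeding values
#'
#' With known variance components, the posterior of the breeding values in
#' the model y = u + e, u ~ N(0, K sigma2_u), e ~ N(0, I sigma2_e) is normal
#' with mean `(I + (sigma2_e/sigma2_u) K^-1)^-1 y` and covariance the same
#' matrix times `sigma2_e`. The mean coincides with the (frequentist) BLUP
#' and equals the algebraically equivalent form
#' `K sigma2_u (K sigma2_u + I sigma2_e)^-1 y`.
#'
#' @param y centered phenotypes, aligned with the ids of `K`.
#' @param K a [relationship_matrix()] (or plain matrix).
#' @param vc a [variance_components()].
#' @return object of class `blup_posterior` with `mean`, `cov`, `vc`, `ids`.
#' @export
blup_posterior <- function(y, K, vc) {
  K <- as_relationship(K)
  stopifnot(inherits(vc, "variance_components"))
  n <- length(y)
  if (n != nrow(K$K)) stopf("y and K dimensions differ")
  M <- blup_smoother(K$K, vc)
  mean <- unname(drop(M %*% y))
  cov <- unname(M * vc$sigma2_e)
  cov <- (cov + t(cov)) / 2
  structure(list(mean = mean, cov = cov, vc = vc, ids = K$ids),
            class = "blup_posterior")
}

# M = (I + (sigma2_e/sigma2_u) K^-1)^-1, computed without forming K^-1:
# M = K sigma2_u (K sigma2_u + I sigma2_e)^-1
blup_smoother <- function(K, vc) {
  n <- nrow(K)
  V <- K * vc$sigma2_u + diag(vc$sigma2_e, n)
  ok <- tryCatch({qr(V)$rank == n}, error = function(e) FALSE)
  if (!ok) stopf("singular relationship matrix: apply nearest_psd() or bending first")
  (K * vc$sigma2_u) %*% solve(V)
}

#' @export
print.blup_posterior <- function(x, ...) {
  h2 <- if (is.null(x$vc)) "multi-trait" else sprintf("h2 = %.3f", x$vc$h2)
  cat(sprintf("<blup_posterior: %d effects, %s>\n", length(x$mean), h2))
  cat(sprintf("  posterior mean range [%.4f, %.4f], mean posterior sd %.4f\n",
              min(x$mean), max(x$mean), mean(sqrt(diag(x$cov)))))
  invisible(x)
}

#' @export
summary.blup_posterior <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd <- sqrt(diag(object$cov))
  data.frame(id = object$ids, mean = object$mean, sd = sd,
             lower = object$mean - z * sd, upper = object$mean + z * sd)
}

#' Single-kernel maximum likelihood variance components
#'
#' Maximizes the likelihood of centered phenotypes under
#' y ~ N(0, K sigma2_u + I sigma2_e) by eigendecomposing K once and profiling
#' the residual variance out, leaving a one-dimensional optimization of the
#' variance ratio on the log scale (bounds 1e-6 to 1e6, tolerance 1e-10; the
#' bounds are expanded once if the optimum hits them).
#'
#' @param y phenotypes (centered internally by their sample mean; the model
#'   carries no fixed effects).
#' @param K a [relationship_matrix()] or plain matrix.
#' @return a [variance_components()] with attribute `"loglik"`.
#' @export
ml_single_kernel <- function(y, K) {
  K <- as_relationship(K)
  n <- length(y)
  if (n < 10) stopf("need at least 10 observations")
  if (n != nrow(K$K)) stopf("y and K dimensions differ")
  y <- y - mean(y)
  e <- eigen(K$K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  # centering annihilates the data along any null eigendirection of K that is
  # confounded with the mean (a centered-marker G always has one); keeping
  # such a direction makes the profile likelihood unbounded in the ratio
  keep <- !(d < 1e-10 * max(d) & yt^2 < 1e-14 * sum(yt^2))
  d <- d[keep]; yt <- yt[keep]
  ne <- length(yt)
  negprof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    s2e <- mean(yt^2 / w)
    0.5 * (ne * log(s2e) + sum(log(w)))
  }
  lo <- log(1e-6); hi <- log(1e6)
  for (attempt in 1:2) {
    opt <- stats::optimize(negprof, c(lo, hi), tol = 1e-10)
    at_edge <- min(opt$minimum - lo, hi - opt$minimum) < 1e-3
    if (!at_edge) break
    lo <- lo - log(1e3); hi <- hi + log(1e3)
  }
  if (at_edge) stopf("variance-ratio optimization did not converge (ratio %.3g at expanded bound)",
                     exp(opt$minimum))
  lam <- exp(opt$minimum)
  s2e <- mean(yt^2 / (lam * d + 1))
  vc <- variance_components(sigma2_u = lam * s2e, sigma2_e = s2e)
  attr(vc, "loglik") <- -opt$objective - ne / 2 * (log(2 * pi) + 1)
  vc
}

#' Sampling moments of BLUP when selection distorts the phenotypes
#'
#' BLUP is the fixed linear map `M = (I + (sigma2_e/sigma2_u) K^-1)^-1`
#' applied to the data, so if selection changes the phenotype moments to
#' `E_s(y)` and `Var_s(y)`, the predictor's moments become `M E_s(y)` and
#' `M Var_s(y) M'`.
#'
#' @param E_s_y post-selection mean vector of the phenotypes.
#' @param Var_s_y post-selection covariance matrix of the phenotypes.
#' @param K a [relationship_matrix()] or plain matrix.
#' @param vc a [variance_components()].
#' @return list with `mean` and `cov` of the BLUP vector under selection.
#' @export
blup_moments_under_selection <- function(E_s_y, Var_s_y, K, vc) {
  K <- as_relationship(K)
  n <- nrow(K$K)
  Var_s_y <- as.matrix(Var_s_y)
  if (length(E_s_y) != n || any(dim(Var_s_y) != n)) stopf("moment dimensions must match K")
  M <- blup_smoother(K$K, vc)
  list(mean = unname(drop(M %*% E_s_y)),
       cov = unname(M %*% Var_s_y %*% t(M)))
}
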