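# Stabilizing (nor-optimal) selection on a multivariate normal: closed-form
# post-selection distribution, the centripetal-selection coefficient, and the
# canonical phenotype/breeding-value bivariate case.

#' Nor-optimal selection specification
#'
#' Selection acts on the components `sel_idx` of a multivariate normal
#' vector through the Gaussian fitness
#' `exp(-(y_sel - lambda)' Gamma^-1 (y_sel - lambda)/2)`.
#'
#' @param m pre-selection mean vector.
#' @param V pre-selection covariance matrix (positive definite).
#' @param sel_idx indices of the components under selection.
#' @param lambda_opt optimum vector (length of `sel_idx`).
#' @param Gamma sharpness matrix, positive definite on the selected block;
#'   `Inf` (scalar) is the explicit no-selection sentinel.
#' @return object of class `nor_optimal_spec`.
#' @export
nor_optimal_spec <- function(m, V, sel_idx, lambda_opt, Gamma) {
  m <- as.numeric(m); V <- as.matrix(V)
  if (!is_symmetric(V)) stopf("V must be symmetric")
  if (length(m) != nrow(V)) stopf("m and V dimensions differ")
  if (any(sel_idx < 1 | sel_idx > length(m))) stopf("sel_idx out of range")
  no_sel <- length(Gamma) == 1 && is.infinite(Gamma[1])
  if (!no_sel) {
    if (length(Gamma) == 1 && !is.matrix(Gamma)) Gamma <- matrix(Gamma, 1, 1)
    if (nrow(Gamma) != length(sel_idx)) stopf("Gamma and sel_idx dimensions differ")
    ev <- eigen((Gamma + t(Gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stopf("Gamma must be positive definite")
  }
  structure(list(m = m, V = V, sel_idx = as.integer(sel_idx),
                 lambda_opt = as.numeric(lambda_opt), Gamma = Gamma,
                 no_selection = no_sel),
            class = "nor_optimal_spec")
}

# Embedded block precision: Gamma^-1 on the selected block, zero elsewhere.
# Stored directly as the generalized inverse; the full Gamma_0 is singular by
# construction and is never inverted.
gamma0_minus <- function(spec) {
  n <- length(spec$m)
  G0m <- matrix(0, n, n)
  if (!spec$no_selection) {
    G0m[spec$sel_idx, spec$sel_idx] <- solve(spec$Gamma)
  }
  G0m
}

#' Post-selection distribution under nor-optimal selection
#'
#' Survivors of Gaussian stabilizing selection remain multivariate normal:
#' with embedded precision `G0m` (the sharpness inverse on the selected
#' block, zeros elsewhere) and padded optimum `lambda0`,
#' `V_s = (G0m + V^-1)^-1` and `m_s = V_s (G0m lambda0 + V^-1 m)`.
#'
#' @param spec a [nor_optimal_spec()].
#' @return list with post-selection mean `m_s` and covariance `V_s`.
#' @export
post_selection_distribution <- function(spec) {
  stopifnot(inherits(spec, "nor_optimal_spec"))
  if (spec$no_selection) return(list(m_s = spec$m, V_s = spec$V))
  n <- length(spec$m)
  Vinv <- solve(spec$V)
  G0m <- gamma0_minus(spec)
  lambda0 <- rep(0, n); lambda0[spec$sel_idx] <- spec$lambda_opt
  Vs <- solve(G0m + Vinv)
  Vs <- (Vs + t(Vs)) / 2
  ms <- drop(Vs %*% (G0m %*% lambda0 + Vinv %*% spec$m))
  list(m_s = ms, V_s = Vs)
}

#' Coefficient of centripetal selection
#'
#' In the scalar case, `S = V / (V + gamma)` is the fraction of variance
#' removed by nor-optimal selection with sharpness `gamma`, and `1 - S =
#' gamma / (V + gamma)` the fraction remaining. `gamma = Inf` means no
#' selection (`S = 0`).
#'
#' @param V pre-selection variance (> 0).
#' @param gamma sharpness (> 0, possibly `Inf`).
#' @return `S` in `[0, 1)`.
#' @export
centripetal_coefficient <- function(V, gamma) {
  if (!(V > 0)) stopf("V must be > 0")
  if (!(gamma > 0)) stopf("gamma must be > 0")
  if (is.infinite(gamma)) return(0)
  V / (V + gamma)
}

#' Phenotype / breeding-value moments after one round of nor-optimal selection
#'
#' Standardized single-trait setting y = u + e with `u ~ N(0, h2)`,
#' `e ~ N(0, 1 - h2)`; phenotypic selection towards `lambda` with sharpness
#' `gamma` gives `S = 1/(1 + gamma)` and post-selection joint moments
#' `E_s(y, u) = (lambda S, h2 lambda S)`,
#' `Var_s = [[1-S, h2(1-S)], [h2(1-S), h2(1 - h2 S)]]`. The conditional
#' moments of `u` given `y` are unchanged by selection
#' (`E_s(u|y) = h2 y`, `Var_s(u|y) = h2 (1 - h2)`), so selection is ignorable
#' for learning a breeding value from its own phenotype, while the additive
#' variance shrinks by the factor `1 - h2 S`.
#'
#' @param h2 heritability in (0, 1).
#' @param lambda_opt selection optimum (standardized trait units).
#' @param gamma sharpness (> 0, possibly `Inf`).
#' @return list with `S`, joint `mean` (y, u), joint `cov`, and the
#'   conditional pieces `cond_slope` (E_s(u|y) = cond_slope * y) and
#'   `cond_var`.
#' @export
phenotype_breeding_value_case <- function(h2, lambda_opt, gamma) {
  if (h2 <= 0 || h2 >= 1) stopf("h2 must be in (0, 1)")
  S <- centripetal_coefficient(1, gamma)
  mean_s <- c(y = lambda_opt * S, u = h2 * lambda_opt * S)
  cov_s <- matrix(c(1 - S, h2 * (1 - S),
                    h2 * (1 - S), h2 * (1 - h2 * S)), 2, 2,
                  dimnames = list(c("y", "u"), c("y", "u")))
  list(S = S, mean = mean_s, cov = cov_s, cond_slope = h2,
       cond_var = h2 * (1 - h2))
}
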