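# Multi-trait sequential culling: Kronecker-structured multi-trait BLUP,
# orthant-probability fitness for culled candidates, joint posterior over
# selected and unselected breeding values, and Metropolis samplers.
#
# Stacking convention is trait-major throughout: a vector over traits and
# individuals is (trait 1 for all individuals, trait 2 for all, ...), i.e.
# `as.vector(Y)` for an individuals x traits matrix Y.

#' Sequential culling rule
#'
#' A candidate is measured for the last trait only if its phenotype exceeds
#' the per-trait culling level for every earlier trait.
#'
#' @param thresholds numeric vector `t_1 .. t_(T-1)` of culling levels
#'   (trait units, finite).
#' @return object of class `culling_spec`.
#' @export
culling_spec <- function(thresholds) {
  if (any(!is.finite(thresholds))) stopf("culling thresholds must be finite")
  structure(list(thresholds = as.numeric(thresholds)), class = "culling_spec")
}

#' Multi-trait model over selected and culled candidates
#'
#' @param covariance a [multitrait_covariance()] (G0, R0).
#' @param K [relationship_matrix()] over all candidates.
#' @param sel_idx indices (into the rows of `K`) of the fully observed
#'   candidates; the complement was culled.
#' @param Y_sel phenotype matrix of the selected candidates,
#'   `length(sel_idx)` x T, columns = traits.
#' @return object of class `multitrait_model`.
#' @export
multitrait_model <- function(covariance, K, sel_idx, Y_sel) {
  stopifnot(inherits(covariance, "multitrait_covariance"))
  K <- as_relationship(K)
  Y_sel <- as.matrix(Y_sel)
  Tn <- nrow(covariance$G0)
  sel_idx <- sort(unique(as.integer(sel_idx)))
  if (any(sel_idx < 1 | sel_idx > nrow(K$K))) stopf("sel_idx out of range")
  if (nrow(Y_sel) != length(sel_idx) || ncol(Y_sel) != Tn)
    stopf("Y_sel must be %d x %d", length(sel_idx), Tn)
  structure(list(covariance = covariance, K = K, sel_idx = sel_idx,
                 nsel_idx = setdiff(seq_len(nrow(K$K)), sel_idx),
                 Y_sel = Y_sel, n_traits = Tn),
            class = "multitrait_model")
}

# Posterior mean and covariance of the stacked breeding values g for the
# system  y = g + e,  g ~ N(0, G0 x Ks),  e ~ N(0, R0 x I),
# exploiting the eigendecomposition Ks = U D U' so that every
# eigencomponent k reduces to a T x T solve with matrix (G0 d_k + R0).
kron_gaussian_posterior <- function(G0, R0, Ks, Y) {
  Tn <- nrow(G0); ns <- nrow(Ks)
  e <- eigen(Ks, symmetric = TRUE)
  U <- e$vectors; d <- e$values
  Yt <- crossprod(U, Y)                    # ns x T, eigenbasis per trait
  Mt <- matrix(0, ns, Tn)
  Cblocks <- vector("list", ns)
  for (k in seq_len(ns)) {
    Ak <- G0 * d[k]
    Sk <- Ak + R0
    if (rcond(Sk) < 1e-14) stopf("singular Kronecker system")
    x <- solve(Sk, Yt[k, ])
    Mt[k, ] <- drop(Ak %*% x)
    Cblocks[[k]] <- Ak - Ak %*% solve(Sk, Ak)
  }
  mean_stacked <- as.vector(U %*% Mt)
  # assemble dense covariance W blkdiag(C_k) W', W = I_T x U
  cov <- matrix(0, ns * Tn, ns * Tn)
  for (a in seq_len(Tn)) for (b in seq_len(Tn)) {
    cab <- vapply(Cblocks, function(C) C[a, b], numeric(1))
    cov[((a - 1) * ns + 1):(a * ns), ((b - 1) * ns + 1):(b * ns)] <-
      U %*% (cab * t(U))
  }
  list(mean = mean_stacked, cov = (cov + t(cov)) / 2)
}

#' Multi-trait BLUP posterior of the selected candidates, ignoring culling
#'
#' Posterior of the stacked (trait-major) breeding values of the fully
#' observed candidates under the Kronecker model
#' `g ~ N(0, G0 x K_sel)`, `y | g ~ N(g, R0 x I)`:
#' mean `(G0 x K_sel)(G0 x K_sel + R0 x I)^-1 y`, covariance
#' `(G0 x K_sel)[I - (G0 x K_sel + R0 x I)^-1 (G0 x K_sel)]`. Computed via
#' the eigendecomposition of `K_sel` (equal to the dense computation).
#'
#' @param model a [multitrait_model()].
#' @return a `blup_posterior`-classed object; `mean` and `cov` are on the
#'   stacked trait-major layout.
#' @export
multitrait_blup_sel <- function(model) {
  stopifnot(inherits(model, "multitrait_model"))
  Ks <- model$K$K[model$sel_idx, model$sel_idx, drop = FALSE]
  out <- kron_gaussian_posterior(model$covariance$G0, model$covariance$R0,
                                 Ks, model$Y_sel)
  ids <- as.vector(outer(model$K$ids[model$sel_idx],
                         seq_len(model$n_traits),
                         function(i, t) paste0("trait", t, ":", i)))
  structure(list(mean = out$mean, cov = out$cov, vc = NULL, ids = ids),
            class = "blup_posterior")
}

#' Probability that a candidate was culled, given its breeding values
#'
#' Lower-orthant probability `Pr(y_1 < t_1, ..., y_(T-1) < t_(T-1) | g)`
#' where the early-trait phenotypes are normal around the candidate's
#' breeding values with residual covariance `R0_sub`.
#'
#' @param g_i breeding values of one candidate for the first T-1 traits.
#' @param R0_sub leading (T-1) x (T-1) residual covariance block.
#' @param thresholds culling levels (length T-1).
#' @return probability in `[0, 1]`.
#' @export
culling_survival_prob <- function(g_i, R0_sub, thresholds) {
  R0_sub <- as.matrix(R0_sub)
  if (length(g_i) != length(thresholds) || nrow(R0_sub) != length(g_i))
    stopf("dimension mismatch")
  pmvnorm_lower(thresholds, mean = g_i, sigma = R0_sub)
}

#' Conditional distribution of culled candidates' breeding values
#'
#' Given the selected candidates' stacked breeding values,
#' `m = (I_T x K_ns K_ss^-1) g_sel` and
#' `V = G0 x (K_nn - K_ns K_ss^-1 K_sn)`.
#'
#' @param g_sel stacked (trait-major) breeding values of selected candidates.
#' @param model a [multitrait_model()].
#' @return list with `mean` and `cov` of the stacked unselected vector.
#' @export
conditional_nsel <- function(g_sel, model) {
  stopifnot(inherits(model, "multitrait_model"))
  K <- model$K$K; s <- model$sel_idx; ns <- model$nsel_idx
  Kss <- K[s, s, drop = FALSE]
  if (rcond(Kss) < 1e-14) stopf("singular K_sel,sel block")
  B <- K[ns, s, drop = FALSE] %*% solve(Kss)     # K_ns K_ss^-1
  Tn <- model$n_traits
  Gsel <- matrix(g_sel, ncol = Tn)
  mean <- as.vector(B %*% Gsel)
  Sc <- K[ns, ns, drop = FALSE] - B %*% K[s, ns, drop = FALSE]
  list(mean = mean, cov = kronecker(model$covariance$G0, (Sc + t(Sc)) / 2))
}

#' Joint log posterior over all breeding values under sequential culling
#'
#' `-Q_sel/2 - Q_nsel/2 + Delta`: the Gaussian kernel of the culling-ignored
#' posterior of the selected candidates, the conditional Gaussian prior of
#' the culled candidates, and the sum over culled candidates of the log
#' probability of having been culled given their breeding values. `Delta` is
#' non-increasing in every early-trait breeding value of a culled candidate.
#' Orthant probabilities underflowing 1e-300 are clamped (with a warning).
#'
#' @param g_all stacked trait-major vector over all candidates and traits.
#' @param model a [multitrait_model()].
#' @param culling a [culling_spec()]; `NULL` drops the culling term.
#' @return scalar log density up to an additive constant.
#' @export
multitrait_log_posterior <- function(g_all, model, culling = NULL) {
  stopifnot(inherits(model, "multitrait_model"))
  n <- nrow(model$K$K); Tn <- model$n_traits
  if (length(g_all) != n * Tn) stopf("g_all must have length %d", n * Tn)
  G <- matrix(g_all, n, Tn)
  g_sel <- as.vector(G[model$sel_idx, , drop = FALSE])
  g_nsel <- as.vector(G[model$nsel_idx, , drop = FALSE])
  post <- multitrait_blup_sel(model)
  d <- g_sel - post$mean
  Q_sel <- drop(crossprod(d, solve(post$cov, d)))
  Q_nsel <- 0
  if (length(model$nsel_idx)) {
    cn <- conditional_nsel(g_sel, model)
    dn <- g_nsel - cn$mean
    # generalized inverse: the conditional covariance is singular whenever K
    # is rank-deficient (e.g. clones, centered-marker G); deviations along
    # null directions carry no density and are ignored
    ec <- eigen(cn$cov, symmetric = TRUE)
    pos <- ec$values > 1e-10 * max(ec$values)
    z <- drop(crossprod(ec$vectors[, pos, drop = FALSE], dn))
    Q_nsel <- sum(z^2 / ec$values[pos])
  }
  lp <- -0.5 * (Q_sel + Q_nsel)
  if (!is.null(culling) && length(model$nsel_idx)) {
    th <- culling$thresholds
    R0_sub <- model$covariance$R0[seq_along(th), seq_along(th), drop = FALSE]
    for (i in seq_along(model$nsel_idx)) {
      p <- culling_survival_prob(G[model$nsel_idx[i], seq_along(th)], R0_sub, th)
      if (p < 1e-300) { warning("orthant probability underflow; clamped"); p <- 1e-300 }
      lp <- lp + log(p)
    }
  }
  lp
}

# Gaussian part of the joint posterior as mean/precision over the stacked
# vector, from  p(y_sel | g_sel) p(g_all):
# precision (a,i),(b,j) = G0inv[a,b] Kinv[i,j] + [i = j in sel] R0inv[a,b].
multitrait_gaussian_part <- function(model) {
  K <- model$K$K; n <- nrow(K); Tn <- model$n_traits
  Kinv <- chol2inv(chol(nearest_psd(K)))
  G0inv <- solve(model$covariance$G0)
  R0inv <- solve(model$covariance$R0)
  P <- kronecker(G0inv, Kinv)
  for (a in seq_len(Tn)) for (b in seq_len(Tn)) {
    ia <- (a - 1) * n + model$sel_idx
    ib <- (b - 1) * n + model$sel_idx
    P[cbind(ia, ib)] <- P[cbind(ia, ib)] + R0inv[a, b]
  }
  bvec <- rep(0, n * Tn)
  rhs <- model$Y_sel %*% R0inv           # m x T
  for (a in seq_len(Tn)) bvec[(a - 1) * n + model$sel_idx] <- rhs[, a]
  P <- (P + t(P)) / 2
  Lp <- chol(P)
  mu <- backsolve(Lp, forwardsolve(t(Lp), bvec))
  list(mean = drop(mu), prec = P)
}

#' Metropolis sampler for the sequential-culling posterior
#'
#' Two update schemes over the full stacked vector (all candidates, all
#' traits):
#'
#' * `"independence"`: per-trait independence proposal with mean
#'   `G0_tt K (G0_tt K + c R0_tt I)^-1 y_t` (culled candidates' missing
#'   phenotypes entered at the prior mean 0) and the matching overdispersed
#'   covariance, `c` = `overdispersion`. `mode = "full_mh"` applies the
#'   detailed-balance acceptance ratio with the proposal-density ratio;
#'   `"as_printed"` reproduces the published ratio verbatim (no Hastings
#'   term, culling ratio oriented now-over-prop).
#' * `"blockwise"`: Metropolis-within-Gibbs over candidates, proposing each
#'   candidate's trait block from its exact Gaussian full conditional so the
#'   acceptance ratio reduces to that candidate's culling term (selected
#'   candidates are pure Gibbs draws). This scales to hundreds of
#'   candidates, where whole-vector independence proposals collapse.
#'
#' @param model a [multitrait_model()].
#' @param culling a [culling_spec()] or `NULL` (culling term dropped).
#' @param n_iter iterations (independence) or sweeps (blockwise).
#' @param seed RNG seed (mandatory).
#' @param overdispersion factor on the residual diagonal in the independence
#'   proposal (default 2).
#' @param mode acceptance-ratio mode for the independence scheme.
#' @param scheme `"independence"` or `"blockwise"`.
#' @param verbose log acceptance per 1000-iteration block.
#' @return an [mcmc_chain()]; columns follow the stacked trait-major layout.
#' @export
run_multitrait_sampler <- function(model, culling, n_iter, seed,
                                   overdispersion = 2,
                                   mode = c("full_mh", "as_printed"),
                                   scheme = c("independence", "blockwise"),
                                   verbose = FALSE) {
  mode <- match.arg(mode); scheme <- match.arg(scheme)
  if (scheme == "independence") {
    mt_sampler_independence(model, culling, n_iter, seed, overdispersion, mode, verbose)
  } else {
    mt_sampler_blockwise(model, culling, n_iter, seed, verbose)
  }
}

mt_culling_delta <- function(G, model, culling) {
  if (is.null(culling) || !length(model$nsel_idx)) return(0)
  th <- culling$thresholds
  R0_sub <- model$covariance$R0[seq_along(th), seq_along(th), drop = FALSE]
  s <- 0
  for (i in model$nsel_idx) {
    p <- culling_survival_prob(G[i, seq_along(th)], R0_sub, th)
    s <- s + log(max(p, 1e-300))
  }
  s
}

mt_sampler_independence <- function(model, culling, n_iter, seed, c_over, mode, verbose) {
  K <- model$K$K; n <- nrow(K); Tn <- model$n_traits
  G0 <- model$covariance$G0; R0 <- model$covariance$R0
  # zero-filled phenotypes over all candidates
  Yfull <- matrix(0, n, Tn)
  Yfull[model$sel_idx, ] <- model$Y_sel
  mu <- matrix(0, n, Tn)
  Lt <- vector("list", Tn)    # cholesky of each per-trait proposal covariance
  Pt <- vector("list", Tn)    # its precision
  for (tt in seq_len(Tn)) {
    A <- G0[tt, tt] * K
    Sm <- A + c_over * R0[tt, tt] * diag(n)
    mu[, tt] <- drop(A %*% solve(Sm, Yfull[, tt]))
    Dt <- A - A %*% solve(Sm, A)
    Dt <- nearest_psd((Dt + t(Dt)) / 2, floor = 1e-10)
    Lt[[tt]] <- chol(Dt)
    Pt[[tt]] <- chol2inv(Lt[[tt]])
  }
  gauss <- multitrait_gaussian_part(model)
  log_target_gauss <- function(g) { d <- g - gauss$mean; -0.5 * drop(crossprod(d, gauss$prec %*% d)) }
  log_q <- function(G) {
    s <- 0
    for (tt in seq_len(Tn)) { d <- G[, tt] - mu[, tt]; s <- s - 0.5 * drop(crossprod(d, Pt[[tt]] %*% d)) }
    s
  }
  set.seed(seed)
  Gnow <- mu
  lt_now <- log_target_gauss(as.vector(Gnow))
  del_now <- mt_culling_delta(Gnow, model, culling)
  lq_now <- log_q(Gnow)
  draws <- matrix(NA_real_, n_iter, n * Tn)
  acc <- logical(n_iter); blocks <- character(0)
  for (it in seq_len(n_iter)) {
    Gp <- mu
    for (tt in seq_len(Tn)) Gp[, tt] <- Gp[, tt] + drop(crossprod(Lt[[tt]], stats::rnorm(n)))
    lt_p <- log_target_gauss(as.vector(Gp))
    del_p <- mt_culling_delta(Gp, model, culling)
    lq_p <- log_q(Gp)
    logR <- if (mode == "full_mh") {
      (lt_p + del_p) - (lt_now + del_now) + lq_now - lq_p
    } else {
      (lt_p - lt_now) + (del_now - del_p)
    }
    if (log(stats::runif(1)) <= logR) {
      Gnow <- Gp; lt_now <- lt_p; del_now <- del_p; lq_now <- lq_p; acc[it] <- TRUE
    }
    draws[it, ] <- as.vector(Gnow)
    if (it %% 1000 == 0) {
      line <- sprintf("iter %d: block acceptance %.3f", it, mean(acc[(it - 999):it]))
      blocks <- c(blocks, line); if (verbose) message(line)
    }
  }
  if (n_iter >= 100 && mean(acc) < 0.001)
    warning(sprintf("acceptance rate %.5f; independence proposal poorly matched (consider scheme = 'blockwise')",
                    mean(acc)))
  mcmc_chain(draws, mean(acc), seed = seed, log = blocks)
}

mt_sampler_blockwise <- function(model, culling, n_sweeps, seed, verbose) {
  K <- model$K$K; n <- nrow(K); Tn <- model$n_traits
  gauss <- multitrait_gaussian_part(model)
  P <- gauss$prec; mu <- gauss$mean
  th <- if (is.null(culling)) NULL else culling$thresholds
  R0_sub <- if (is.null(th)) NULL else
    model$covariance$R0[seq_along(th), seq_along(th), drop = FALSE]
  # per-candidate conditional pieces
  idx <- lapply(seq_len(n), function(i) (seq_len(Tn) - 1) * n + i)
  Pii_chol <- lapply(idx, function(ix) chol(P[ix, ix, drop = FALSE]))
  Prows <- lapply(idx, function(ix) P[ix, , drop = FALSE])
  is_culled <- rep(FALSE, n); is_culled[model$nsel_idx] <- TRUE
  set.seed(seed)
  g <- mu
  delta_i <- function(gi) {
    if (is.null(th)) return(0)
    log(max(culling_survival_prob(gi[seq_along(th)], R0_sub, th), 1e-300))
  }
  del_now <- vapply(seq_len(n), function(i) if (is_culled[i]) delta_i(g[idx[[i]]]) else 0,
                    numeric(1))
  draws <- matrix(NA_real_, n_sweeps, n * Tn)
  n_mh <- 0; n_acc <- 0
  for (sw in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      ix <- idx[[i]]
      Lc <- Pii_chol[[i]]
      # conditional mean given the rest: cross-coupling term only
      r_i <- drop(Prows[[i]] %*% (g - mu)) -
        drop(P[ix, ix, drop = FALSE] %*% (g[ix] - mu[ix]))
      cmean <- mu[ix] - backsolve(Lc, forwardsolve(t(Lc), r_i))
      gprop <- cmean + backsolve(Lc, stats::rnorm(Tn))
      if (is_culled[i] && !is.null(th)) {
        n_mh <- n_mh + 1
        dn <- delta_i(gprop)
        if (log(stats::runif(1)) <= dn - del_now[i]) {
          g[ix] <- gprop; del_now[i] <- dn; n_acc <- n_acc + 1
        }
      } else {
        g[ix] <- gprop    # exact Gibbs draw
      }
    }
    draws[sw, ] <- g
  }
  rate <- if (n_mh > 0) n_acc / n_mh else 1
  mcmc_chain(draws, rate, seed = seed,
             log = sprintf("blockwise: %d sweeps, MH acceptance %.3f", n_sweeps, rate))
}
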