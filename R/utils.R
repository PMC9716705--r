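# Small numerical helpers shared across modules.

#' Log-sum-exp
#'
#' Numerically stable `log(sum(exp(x)))`; returns `-Inf` for an all `-Inf`
#' input.
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return scalar.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Trapezoid-rule integral on an irregular grid
#'
#' @param x strictly increasing abscissae.
#' @param y function values at `x`.
#' @return scalar integral estimate.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# log(1 - pnorm(z)) without catastrophic underflow
log1mPhi <- function(z) stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)

# symmetric check used by several constructors
is_symmetric <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

# derive a 32-bit sub-seed from a base seed and a stream index
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * k) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
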