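# Core domain types: relationship matrices, variance components,
# multi-trait covariances, missingness patterns, PSD repair.

#' Relationship matrix
#'
#' A symmetric positive semi-definite matrix of relatedness coefficients among
#' individuals, either pedigree-derived (numerator relationship matrix A),
#' marker-derived (genomic relationship matrix G) or the identity.
#'
#' @param K square symmetric numeric matrix.
#' @param ids character vector of individual identifiers (defaults to
#'   `rownames(K)` or `1..n`).
#' @param kind one of `"pedigree"`, `"genomic"`, `"identity"`.
#' @param repair if `TRUE` (default) apply [nearest_psd()] when `K` has
#'   eigenvalues below `-1e-8` times the largest one fails validation;
#'   slightly negative eigenvalues from round-off are floored.
#' @return an object of class `relationship_matrix` with elements `K`, `ids`,
#'   `kind`.
#' @export
relationship_matrix <- function(K, ids = NULL, kind = c("genomic", "pedigree", "identity"),
                                repair = TRUE) {
  kind <- match.arg(kind)
  if (!is.matrix(K) || nrow(K) != ncol(K)) stopf("K must be a square matrix")
  if (!is_symmetric(K)) stopf("K must be symmetric (tolerance 1e-10)")
  K <- (K + t(K)) / 2
  if (is.null(ids)) ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  if (length(ids) != nrow(K)) stopf("ids must have one entry per row of K")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    if (!repair) stopf("K is not positive semi-definite (min eigenvalue %.3g)", min(ev))
    K <- nearest_psd(K)
  } else if (min(ev) < 0 && repair) {
    K <- nearest_psd(K)
  }
  if (kind == "pedigree" && any(diag(K) < 1 - 1e-8)) {
    stopf("pedigree relationship matrix must have diagonal >= 1")
  }
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = ids, kind = kind), class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix: %s, %d individuals>\n", x$kind, length(x$ids)))
  cat(sprintf("  mean diagonal %.4f, range of off-diagonals [%.4f, %.4f]\n",
              mean(diag(x$K)),
              min(x$K[upper.tri(x$K)]), max(x$K[upper.tri(x$K)])))
  invisible(x)
}

as_relationship <- function(K) {
  if (inherits(K, "relationship_matrix")) return(K)
  relationship_matrix(as.matrix(K))
}

#' Genomic relationship matrix from marker codes
#'
#' Builds G = XX'/p where each marker column of `X` is centered and divided by
#' its sample standard deviation. Zero-variance columns carry no signal: they
#' are dropped and `p` counts only the retained columns, which keeps the mean
#' diagonal of G near 1.
#'
#' @param X numeric matrix of marker codes (0/1 or 0/1/2), individuals in rows.
#' @param ids optional individual identifiers (default `rownames(X)`).
#' @return a [relationship_matrix()] of kind `"genomic"`.
#' @export
genomic_relationship <- function(X, ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("need at least 2 individuals")
  if (!is.numeric(X)) stopf("marker codes must be numeric")
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # population (1/n) standard deviation, so a standardized column has
  # mean square exactly 1 and diag(G) averages 1
  sds <- sqrt(colMeans(Xc^2))
  keep <- sds > 0
  if (!any(keep)) stopf("no informative markers")
  Z <- sweep(Xc[, keep, drop = FALSE], 2, sds[keep], "/")
  p <- sum(keep)
  K <- tcrossprod(Z) / p
  if (is.null(ids)) ids <- rownames(X)
  relationship_matrix(K, ids = ids, kind = "genomic")
}

#' Pedigree (numerator) relationship matrix
#'
#' Recursive tabular method. Founders (unknown parents, coded 0, NA or "")
#' get diagonal 1; an individual's relationship with any previous individual
#' is the average of its parents' relationships, and its own diagonal is
#' 1 + half the relationship between its parents.
#'
#' @param pedigree data frame with columns id, sire, dam (in that order).
#'   Parents must be listed before their offspring; unknown parents are 0,
#'   `NA` or the empty string.
#' @return a [relationship_matrix()] of kind `"pedigree"`.
#' @export
pedigree_relationship <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  if (ncol(ped) < 3) stopf("pedigree needs id, sire, dam columns")
  id <- as.character(ped[[1]])
  if (anyDuplicated(id)) stopf("duplicated individual ids in pedigree")
  unk <- function(v) { v <- as.character(v); v[is.na(v) | v == "0" | v == ""] <- NA; v }
  sire <- unk(ped[[2]]); dam <- unk(ped[[3]])
  n <- length(id)
  idx <- function(p, i) {
    if (is.na(p[i])) return(0L)
    j <- match(p[i], id)
    if (is.na(j)) stopf("parent '%s' of '%s' not in pedigree", p[i], id[i])
    if (j >= i) stopf("pedigree not topologically ordered (or cyclic) at '%s'", id[i])
    j
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx(sire, i); d <- idx(dam, i)
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (s > 0) a <- a + A[j, s]
        if (d > 0) a <- a + A[j, d]
        A[i, j] <- A[j, i] <- a / 2
      }
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  relationship_matrix(A, ids = id, kind = "pedigree")
}

#' Repair a symmetric matrix to positive semi-definiteness
#'
#' Symmetrizes the input as (M + M')/2, then raises every eigenvalue below
#' `floor` times the largest eigenvalue up to that floor value and
#' reconstructs. A matrix whose smallest eigenvalue already clears the floor
#' is returned unchanged (beyond symmetrization). Idempotent.
#'
#' @param M square numeric matrix.
#' @param floor relative eigenvalue floor (default `1e-8`), chosen so repaired
#'   matrices are numerically invertible without visible distortion.
#' @return symmetric positive semi-definite matrix.
#' @export
nearest_psd <- function(M, floor = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("M must be a square matrix")
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam_max <- max(e$values)
  lo <- floor * max(lam_max, .Machine$double.eps)
  if (min(e$values) >= lo) return(M)
  lam <- pmax(e$values, lo)
  R <- e$vectors %*% (lam * t(e$vectors))
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(M)
  R
}

#' Variance components of a single-kernel model
#'
#' @param sigma2_u genetic variance (trait units squared).
#' @param sigma2_e residual variance (trait units squared).
#' @return object of class `variance_components` with fields `sigma2_u`,
#'   `sigma2_e` and derived heritability `h2 = sigma2_u/(sigma2_u+sigma2_e)`.
#' @export
variance_components <- function(sigma2_u, sigma2_e) {
  if (!(sigma2_u > 0) || !(sigma2_e > 0)) stopf("variances must be > 0")
  h2 <- sigma2_u / (sigma2_u + sigma2_e)
  structure(list(sigma2_u = sigma2_u, sigma2_e = sigma2_e, h2 = h2),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components: sigma2_u = %.4f, sigma2_e = %.4f, h2 = %.4f>\n",
              x$sigma2_u, x$sigma2_e, x$h2))
  invisible(x)
}

#' Multi-trait covariance structure
#'
#' Holds the between-trait genetic (G0) and residual (R0) covariance matrices,
#' their sum V0 and the implied matrix of phenotypic correlations Psi. Inputs
#' are symmetrized as (M + M')/2 (covariance matrices are symmetric by
#' definition, so a printed asymmetric cell is treated as a typo) and PSD
#' repaired if needed.
#'
#' @param G0 between-trait genetic covariance matrix (traits x traits).
#' @param R0 between-trait residual covariance matrix.
#' @return object of class `multitrait_covariance` with fields `G0`, `R0`,
#'   `V0`, `Psi`.
#' @export
multitrait_covariance <- function(G0, R0) {
  G0 <- nearest_psd(as.matrix(G0))
  R0 <- nearest_psd(as.matrix(R0))
  if (!all(dim(G0) == dim(R0))) stopf("G0 and R0 must have the same dimension")
  V0 <- G0 + R0
  Psi <- stats::cov2cor(V0)
  if (any(abs(Psi[upper.tri(Psi)]) >= 1)) stopf("degenerate phenotypic correlation")
  structure(list(G0 = G0, R0 = R0, V0 = V0, Psi = Psi),
            class = "multitrait_covariance")
}

#' Missingness pattern
#'
#' Binary indicator aligned with the complete-data layout: 1 = observed,
#' 0 = missing.
#'
#' @param r binary vector or matrix.
#' @return object of class `missingness_pattern`.
#' @export
missingness_pattern <- function(r) {
  if (!all(r %in% c(0, 1))) stopf("missingness entries must be 0 or 1")
  if (!any(r == 1)) stopf("at least one entry must be observed")
  structure(list(r = r), class = "missingness_pattern")
}
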