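# Seeded generators emulating the data structures the selection scenarios
# consume: correlated-trait truncation samples, genomic populations with an
# inbred-line marker structure, pedigree populations, and Kronecker
# multi-trait phenotypes with sequential culling. Every generator is a pure
# function of its arguments and the mandatory seed.

#' Simulate correlated-trait truncation selection
#'
#' Draws `n` iid bivariate normal pairs (traits A and B); trait B is observed
#' iff the pair's trait-A value strictly exceeds `threshold`. Trait-A records
#' are then discarded from the available data, emulating selection on records
#' never presented to the analyst.
#'
#' @param n number of pairs.
#' @param rho correlation, |rho| < 1.
#' @param mu_A,mu_B trait means (default 0).
#' @param threshold truncation threshold on trait A (`-Inf` = no selection).
#' @param seed RNG seed (mandatory).
#' @return list with `pairs` (n x 2 matrix of complete data), `pattern`
#'   (a [missingness_pattern()] over trait-B records), and `y_B_obs`
#'   (observed trait-B records).
#' @export
simulate_bivariate_selection <- function(n, rho, mu_A = 0, mu_B = 0, threshold, seed) {
  if (n < 1) stopf("n must be >= 1")
  if (abs(rho) >= 1) stopf("|rho| must be < 1")
  if (missing(seed)) stopf("seed is mandatory")
  set.seed(seed)
  zA <- stats::rnorm(n)
  zB <- rho * zA + sqrt(1 - rho^2) * stats::rnorm(n)
  pairs <- cbind(A = mu_A + zA, B = mu_B + zB)
  obs <- pairs[, 1] > threshold
  list(pairs = pairs,
       pattern = missingness_pattern(as.numeric(obs)),
       y_B_obs = pairs[obs, 2])
}

#' Simulate a genotyped population with an additive genetic architecture
#'
#' Binary markers (inbred-line emulation: fully homozygous 0/1 genotypes;
#' `ploidy = "diploid"` gives 0/1/2 codes) with per-locus allele frequencies
#' uniform in `maf_range`. Breeding values are `g = Z beta` with
#' `beta ~ N(0, sigma2_g / p)` on the centered/standardized marker matrix
#' `Z`, the equivalent-model counterpart of `g ~ N(0, G sigma2_g)` with
#' `G = ZZ'/p`; phenotypes add `N(0, sigma2_e)` residuals.
#'
#' @param n individuals.
#' @param p markers (>= 2).
#' @param maf_range allele-frequency range (default `c(0.1, 0.5)`).
#' @param sigma2_g,sigma2_e genetic and residual variances.
#' @param seed RNG seed (mandatory).
#' @param ploidy `"inbred"` (default) or `"diploid"`.
#' @return list with `X` (marker codes), `g` (true breeding values),
#'   `y` (phenotypes).
#' @export
simulate_genomic_population <- function(n, p, maf_range = c(0.1, 0.5),
                                        sigma2_g, sigma2_e, seed,
                                        ploidy = c("inbred", "diploid")) {
  if (p < 2) stopf("p must be >= 2")
  if (missing(seed)) stopf("seed is mandatory")
  ploidy <- match.arg(ploidy)
  set.seed(seed)
  f <- stats::runif(p, maf_range[1], maf_range[2])
  X <- if (ploidy == "inbred") {
    matrix(stats::rbinom(n * p, 1, rep(f, each = n)), n, p)
  } else {
    matrix(stats::rbinom(n * p, 2, rep(f, each = n)), n, p)
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  Z <- scale(X[, keep, drop = FALSE])
  beta <- stats::rnorm(sum(keep), 0, sqrt(sigma2_g / sum(keep)))
  g <- if (sigma2_g > 0) drop(Z %*% beta) else rep(0, n)
  y <- g + stats::rnorm(n, 0, sqrt(sigma2_e))
  rownames(X) <- paste0("ind", seq_len(n))
  list(X = X, g = g, y = y)
}

#' Simulate a random-mating pedigree population
#'
#' Forward simulation: `founders` unrelated individuals, then `generations`
#' rounds in which random sire/dam pairs from the previous generation each
#' produce `offspring_per_mating` offspring. Breeding values follow the
#' pedigree: founders draw `N(0, sigma2_a)`, offspring get the parent
#' average plus a Mendelian-sampling deviation with variance `sigma2_a/2`
#' (no inbreeding adjustment; matings avoid selfing). Phenotypes are
#' `a + e` with residual variance chosen so that heritability is `h2` under
#' unit phenotypic variance.
#'
#' @param founders number of founders (>= 2).
#' @param generations number of offspring generations.
#' @param offspring_per_mating offspring per mating pair.
#' @param h2 heritability in (0, 1); `sigma2_a = h2`, `sigma2_e = 1 - h2`.
#' @param seed RNG seed (mandatory).
#' @return list with `pedigree` (id, sire, dam), `A` (pedigree
#'   [relationship_matrix()]), `a` (true breeding values), `y` (phenotypes).
#' @export
simulate_pedigree_population <- function(founders, generations = 1,
                                         offspring_per_mating = 2, h2 = 0.33,
                                         seed) {
  if (founders < 2) stopf("need at least 2 founders")
  if (missing(seed)) stopf("seed is mandatory")
  set.seed(seed)
  sigma2_a <- h2; sigma2_e <- 1 - h2
  id <- paste0("F", seq_len(founders))
  sire <- rep(NA_character_, founders); dam <- rep(NA_character_, founders)
  a <- stats::rnorm(founders, 0, sqrt(sigma2_a))
  prev <- id
  counter <- 0
  for (gen in seq_len(generations)) {
    n_mate <- max(1, floor(length(prev) / 2))
    perm <- sample(prev)
    newids <- character(0); newsire <- character(0); newdam <- character(0); newa <- numeric(0)
    for (mt in seq_len(n_mate)) {
      s <- perm[2 * mt - 1]; d <- perm[2 * mt]
      if (is.na(d)) next
      for (o in seq_len(offspring_per_mating)) {
        counter <- counter + 1
        kid <- paste0("G", gen, "_", counter)
        pa <- (a[match(s, id)] + a[match(d, id)]) / 2 +
          stats::rnorm(1, 0, sqrt(sigma2_a / 2))
        id <- c(id, kid); sire <- c(sire, s); dam <- c(dam, d); a <- c(a, pa)
        newids <- c(newids, kid)
      }
    }
    prev <- newids
    if (!length(prev)) break
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  A <- pedigree_relationship(ped)
  y <- a + stats::rnorm(length(a), 0, sqrt(sigma2_e))
  list(pedigree = ped, A = A, a = a, y = y)
}

#' Simulate Kronecker-structured multi-trait phenotypes
#'
#' Stacked breeding values drawn from `N(0, G0 x K)` and residuals from
#' `N(0, R0 x I)`; phenotypes are their sum. Non-PSD covariance inputs are
#' repaired with a warning.
#'
#' @param G0,R0 between-trait covariance matrices (T x T).
#' @param K relationship matrix (or [relationship_matrix()]) over
#'   individuals.
#' @param seed RNG seed (mandatory).
#' @return list with `Y` (n x T phenotypes), `G_true` (n x T breeding
#'   values).
#' @export
simulate_multitrait <- function(G0, R0, K, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  fix <- function(M, nm) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev))) {
      warning(sprintf("%s not PSD; repaired", nm)); nearest_psd(M)
    } else (M + t(M)) / 2
  }
  G0 <- fix(G0, "G0"); R0 <- fix(R0, "R0")
  K <- as_relationship(K)
  n <- nrow(K$K); Tn <- nrow(G0)
  set.seed(seed)
  Lk <- chol(nearest_psd(K$K, floor = 1e-10))
  Lg <- chol(nearest_psd(G0, floor = 1e-10))
  # G x K draw: vec-form, trait-major = K-chol on the left of an n x T normal
  Z <- matrix(stats::rnorm(n * Tn), n, Tn)
  G_true <- crossprod(Lk, Z) %*% Lg
  Lr <- chol(nearest_psd(R0, floor = 1e-10))
  E <- matrix(stats::rnorm(n * Tn), n, Tn) %*% Lr
  list(Y = G_true + E, G_true = G_true)
}

#' Apply a sequential culling rule to a multi-trait phenotype matrix
#'
#' A candidate enters the fully observed set iff its phenotype strictly
#' exceeds the threshold for every early trait; the last trait is masked
#' (`NA`) for everyone else.
#'
#' @param Y n x T phenotype matrix.
#' @param thresholds culling levels for traits 1..T-1.
#' @return list with `sel_idx`, `nsel_idx`, `Y_masked` (last trait `NA` for
#'   culled candidates), and `pattern` (a [missingness_pattern()]).
#' @export
apply_sequential_culling <- function(Y, thresholds) {
  Y <- as.matrix(Y)
  Tn <- ncol(Y)
  if (length(thresholds) != Tn - 1) stopf("need %d thresholds", Tn - 1)
  keep <- rep(TRUE, nrow(Y))
  for (j in seq_along(thresholds)) keep <- keep & (Y[, j] > thresholds[j])
  sel <- which(keep); nsel <- which(!keep)
  Ym <- Y
  if (length(nsel)) Ym[nsel, Tn] <- NA
  r <- matrix(1, nrow(Y), Tn)
  r[nsel, Tn] <- 0
  list(sel_idx = sel, nsel_idx = nsel, Y_masked = Ym,
       pattern = missingness_pattern(r))
}
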