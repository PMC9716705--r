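---
title: "Selection-aware Bayesian inference for quantitative traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-aware Bayesian inference for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selinf)
```

# The model

Let $y$ be phenotypes and $\theta$ the unknowns (means, variance components,
breeding values). Without selection, inference is the usual
$p(\theta \mid y) \propto p(y \mid \theta)\,p(\theta)$. Selection is encoded
through a *fitness function* $H(y \mid \varphi)$ — the probability, up to
scale, that an individual with phenotypes $y$ survives the selection process
and therefore has its records observed. Writing $r$ for the binary
missingness pattern, the joint density of observed data, pattern and
parameters factorizes so that the posterior under selection is

$$
p_s(\theta \mid y_{obs}, r) \;\propto\;
p(y_{obs}\mid\theta)\,p(\theta)\,
H(y_{obs}, \varphi, \theta),
\qquad
H(y_{obs},\varphi,\theta) = \int \Pr(r \mid y_{obs}, y_{miss}, \varphi,\theta)\,
p(y_{miss}\mid y_{obs},\theta)\, dy_{miss}.
$$

Two structural facts drive everything in the package:

* **Ignorability.** If $\Pr(r \mid \cdot)$ depends on the *observed* data
  only and $\varphi$ is a priori independent of $\theta$, then $H$ is a
  constant in $\theta$ and cancels in the normalization: the posterior, the
  posterior predictive density and posterior model probabilities are all
  exactly unchanged. `check_ignorability()` and the fitness-module tests
  verify these invariances numerically (sup-norm and relative differences
  below $10^{-8}$ on grid posteriors).
* **Non-ignorability.** Whenever the fitness involves missing data or
  $\theta$ itself — every scenario below — the correction term must be kept,
  and it is what the package computes.

All grid-posterior arithmetic is done in log space with log-sum-exp before a
trapezoid normalization: corrections of the form $\sum_i \log[1-\Phi(\cdot)]$
underflow otherwise.

# The four selection scenarios

## Truncation on a correlated, never-observed trait

Records of trait B are available only for individuals whose trait-A value
(recorded elsewhere and never released) exceeded a threshold $t$. With a
bivariate normal trait model and all parameters known except the trait-B
mean $\mu_B$, the corrected log posterior adds
$\sum_i \log[1-\Phi((t-\mu_{A.B,i})/\sqrt{v_{A.B}})]$ to the Gaussian
kernel, with $\mu_{A.B,i}=\mu_A + b(y_{iB}-\mu_B)$,
$b=\rho\sigma_A/\sigma_B$ and $v_{A.B}=\sigma_A^2(1-\rho^2)$
(`example1_log_correction()`, `example1_posterior()`). At $\rho=0$ or
$t=-\infty$ the correction is constant and the naive posterior is recovered
exactly — both limits are tested.

**Grid placement.** The natural anchor is the selection-ignoring posterior
$N(\bar y_B, \sigma_B^2/m)$, and the grid starts at its mean $\pm 8$ of its
posterior standard deviations with 2001 points. That window is, however, far
too narrow once selection is strong: at $\rho=0.8$, $t=1$ the corrected
posterior sits roughly fifteen naive posterior standard deviations below the
naive mean. The grid builders therefore double the half-width until the
density at both edges falls below $10^{-12}$ of the maximum (at most eight
doublings). This keeps quadrature cheap in easy cases without ever clipping
displaced mass.

## Truncation with all retained records above a threshold

When every record presented to the analyst is known to exceed $t$, the
likelihood is a product of truncated normals and the posterior of the mean
is $\propto \exp\{-n(\mu-\bar y)^2/2\sigma^2\}/[1-\Phi((t-\mu)/\sigma)]^n$
(`harville_truncation_posterior()`). It has no closed form; mean, sd, mode
and credible intervals come from the grid. A rejection sampler (wide-normal
proposal, likelihood-ratio acceptance) serves as the independent oracle in
the tests (total-variation agreement within 0.02).

## Pre-selection of genotyping candidates

Only the $m$ candidates whose pedigree BLUP $\hat a_i$ exceeded $t$ were
genotyped. The corrected posterior of their genomic breeding values
multiplies the genomic-BLUP Gaussian by $\exp\{\sum_i \log[1-\Phi(z_i)]\}$,
where $z_i$ standardizes $t$ against the conditional distribution of
$\hat a_i$ given $g_i$:
$z_i = (t - \rho_i(\sigma_{\hat a,i}/\sigma_{g,i})g_i)\,/\,
\sqrt{\sigma^2_{\hat a,i}(1-\sigma^2_{\hat a,i}/\sigma^2_{g,i})}$.

Parameter choices:

* $\rho_{g\hat a}$, the correlation between genomic breeding value and
  pedigree BLUP, defaults to 0.75 (a realistic value for well-recorded populations); it can be set per individual.
* $\sigma^2_{\hat a,i}$ is the sampling variance of the BLUP itself,
  $\sigma_a^2 A_{ii} - C_{a,ii}$ (`blup_reliability_variance()`). The
  homogeneous-information special case $\sigma_{\hat a}=h_a^2
  \sqrt{\sigma^2_a+\sigma^2_e}$ is recovered when all candidates carry equal
  information; the reliability-based form is used because candidates never
  do. The constructor validates $\sigma^2_{\hat a,i}<\sigma^2_{g,i}$, which
  the conditional variance requires.

The posterior is explored with an independence Metropolis sampler whose
proposal is the pedigree-BLUP posterior
$N(\tilde a_{sel}, (I+(\sigma^2_e/\sigma^2_a)A_{sel}^{-1})^{-1}\sigma^2_e)$.
Two acceptance modes are provided. `full_mh` (default) is the correct
independence sampler: target ratio times the proposal-density ratio
$q(g^{now})/q(g^{prop})$. `as_printed` reproduces, verbatim, the acceptance ratio as it has appeared
in print in the animal-breeding literature; that ratio omits the proposal-density ratio, and its
selection-correction factor is oriented now-over-prop (the reciprocal of the
target ratio's orientation). The replication mode exists for fidelity
studies only; every correctness test runs `full_mh`, which is validated
against lattice-normalized posteriors and rejection oracles on 3-candidate
toys (total variation < 0.05) and against the closed-form Gaussian when the
correction is disabled.

## Multi-trait sequential culling

Candidates are measured on trait $j+1$ only if they exceeded culling levels
$t_1..t_j$ on the earlier traits; the analyst receives the full $T$-trait
records of the survivors only. With Kronecker covariances
($g \sim N(0, G_0\otimes K)$, residuals $R_0\otimes I$), the joint log
posterior over all breeding values has three parts: the Gaussian kernel of
the survivors' culling-ignored posterior, the conditional Gaussian prior of
the culled candidates given the survivors, and
$\sum_{i \in culled}\log \Phi_{T-1}(t_1..t_{T-1}\mid g_i, R_0^{(T-1)})$ —
a lower-orthant multivariate normal probability per culled candidate.

Numerical choices:

* **Orthant probabilities** are computed deterministically: the bivariate
  case by the exact single-integral identity
  $\Phi_2(h,k;r)=\Phi(h)\Phi(k)+\frac{1}{2\pi}\int_0^{\arcsin r}
  e^{-(h^2-2hk\sin\tau+k^2)/(2\cos^2\tau)}d\tau$ with adaptive quadrature,
  the trivariate case by conditioning on the first coordinate and
  integrating the conditional bivariate probability. Determinism matters
  because a Metropolis target must return the same value at the same point;
  a deterministic quadrature achieves this with tighter error control than
  seeded quasi-Monte-Carlo at these dimensions ($d \le 3$ is all the model
  needs; higher dimensions are rejected with a clear error). Monte-Carlo
  estimates are used only as independent oracles in tests.
* **Kronecker algebra.** The survivors' posterior is computed through the
  eigendecomposition of $K_{sel}$ (each eigencomponent reduces to a
  $T\times T$ solve) and is tested to equal the dense joint-Gaussian
  computation to $10^{-9}$.
* **Degenerate conditionals.** $K$ may be rank-deficient (clones; any
  centered-marker $G$ has the ones-vector in its null space), making the
  conditional covariance of culled candidates singular. The quadratic form
  uses an eigenvalue pseudo-inverse (relative tolerance $10^{-10}$), and the
  joint Gaussian part is assembled with Cholesky solves.

Two samplers explore the posterior. The *independence* scheme proposes
whole vectors from per-trait smoothers with an overdispersed residual
(factor `overdispersion`, default 2; culled candidates' missing phenotypes
enter at the prior mean 0), with the same `full_mh` / `as_printed` modes as
above. Whole-vector independence proposals collapse as dimension grows, so a
*blockwise* scheme is also provided: a Metropolis-within-Gibbs sweep over
candidates that proposes each candidate's trait block from its exact
Gaussian full conditional, leaving only that candidate's culling term in the
acceptance ratio (survivors are pure Gibbs updates). The blockwise scheme is
what makes the 200-candidate end-to-end experiment below feasible; both
schemes are validated against the same oracles on small toys.

**Relationship-matrix conditioning.** Because a centered-marker $G$ is
always singular, models built directly on such a $G$ mix poorly along its
null directions. Standard practice is *bending* — blending a small multiple
of the identity, $K \leftarrow (1-w)K + wI$ — and the command-line
`multitrait` pipeline applies $w=0.05$ by default (flag `--bend`). The test
fixtures do the same.

## Nor-optimal (stabilizing) selection

Gaussian fitness $H(y_1)=\exp\{-\tfrac12 (y_1-\lambda)'\Gamma^{-1}
(y_1-\lambda)\}$ acting on a subvector of a multivariate normal leaves
survivors normal with $V_s=(\Gamma_0^- + V^{-1})^{-1}$ and
$m_s=V_s(\Gamma_0^-\lambda_0+V^{-1}m)$, where $\Gamma_0^-$ embeds
$\Gamma^{-1}$ in the selected block and is zero elsewhere. $\Gamma_0^-$ is
stored as that block-precision object directly — the full $\Gamma_0$ is
singular by construction and is never inverted. No selection
($\gamma=\infty$) is an explicit sentinel handled exactly, not a large
float. In the standardized phenotype/breeding-value case,
$S = 1/(1+\gamma)$, the joint post-selection moments are
$(\lambda S, h^2\lambda S)$ and
$[[1-S, h^2(1-S)],[h^2(1-S), h^2(1-h^2S)]]$, and the conditional
distribution of the breeding value given the phenotype is unchanged —
stabilizing selection is ignorable for learning $u$ from $y$, but *not* for
the base-population mean, whose posterior becomes
$N((\bar y - \lambda S)/(1-S),\, 1/(m(1-S)))$. A form of that variance sometimes quoted carries the pre-selection sample
size; the package uses the observed (post-selection) sample size $m$ — it is $m$ draws of variance $1-S$ that enter the likelihood.

# BLUP and variance components

`blup_posterior()` returns the Gaussian posterior of breeding values at
known variances (mean $(I+(\sigma^2_e/\sigma^2_u)K^{-1})^{-1}y$, computed in
the equivalent inverse-free form $K\sigma^2_u(K\sigma^2_u+I\sigma^2_e)^{-1}y$).
`ml_single_kernel()` estimates $(\sigma^2_u, \sigma^2_e)$ by profiling the
likelihood down to the variance ratio, optimized on the log scale over
$[10^{-6},10^6]$ to tolerance $10^{-10}$ (bounds expanded once before
declaring failure). Phenotypes are centered by their sample mean first (the
models carry no fixed effects); centering annihilates the data along a null
eigendirection of $K$ confounded with the mean, which would otherwise make
the profile likelihood unbounded, so such degenerate directions are dropped
from the likelihood. `blup_moments_under_selection()` propagates arbitrary
post-selection phenotype moments through the fixed BLUP map, which is how
selection biases a frequentist BLUP even when the Bayesian posterior is
untouched — the "epistemic bias" identity
$E(\hat g\mid g)=(I+(\sigma^2_{e^*}/\sigma^2_g)G^{-1})^{-1}g$ is verified by
simulation in the tests.

# Synthetic data: what it emulates and what it does not

The generators (`simulate_bivariate_selection()`,
`simulate_genomic_population()`, `simulate_pedigree_population()`,
`simulate_multitrait()`, `apply_sequential_culling()`) are pure functions of
their arguments plus a mandatory seed, and reproduce exactly the
distributional assumptions the inference modules state: bivariate normal
pairs with truncation on one member; binary (inbred-line, 0/1) or diploid
(0/1/2) markers with allele frequencies uniform on `maf_range` (default
0.1–0.5) and additive effects $\beta \sim N(0,\sigma^2_g/p)$ on standardized
markers — the equivalent model of $g\sim N(0, G\sigma^2_g)$ with $G=XX'/p$;
pedigree breeding values built by parent-average plus Mendelian sampling;
stacked multi-trait values drawn from $G_0\otimes K$.

They deliberately do *not* emulate linkage and LD structure, minor-allele
frequency spectra of real panels, inbreeding accumulation, genotype-by-
environment interaction, or multi-generation selection response. Passing
tests therefore demonstrate that the estimators and samplers are correct
*under the stated model*, and that the selection corrections recover truth
when the fitness function matches the true missingness process — the
central claim. They cannot show robustness to a misspecified fitness
function, which remains the user's modelling risk.

Default study conditions follow the protocols the scenarios describe:
n = 1000 pairs with $\rho=0.8$ and thresholds 0/1/1.5/2 sd for the
correlated-trait setting; the multi-environment covariance matrices and
culling levels (0, 0.6, 1.3) printed for the wheat analysis are carried as
fixture constants; the end-to-end culling experiment runs at a reduced scale
of 200 candidates, two traits and one culling level at 0 (about half the
candidates culled), 20 replicate seeds — sizes chosen so the whole suite
runs comfortably on a laptop while keeping Monte-Carlo error well inside the
3-standard-error bands the tests use.

# Degenerate inputs and conventions

* Truncation survival uses strict inequality ($y>t$ survives "above"
  selection): the open-interval indicator convention; a measure-zero choice
  for continuous traits, fixed for reproducibility.
* Zero-variance marker columns are dropped and the divisor $p$ counts only
  retained columns, keeping $\mathrm{diag}(G)\approx 1$; a marker matrix
  with no informative column is an error.
* `nearest_psd()` symmetrizes, then floors eigenvalues at $10^{-8}$ of the
  largest (relative floor chosen to make repaired matrices invertible
  without visibly distorting them); it is idempotent and leaves
  already-compliant matrices unchanged. The printed residual covariance of
  the wheat analysis contains one asymmetric cell; symmetrization
  $(M+M')/2$ resolves it, as covariance matrices are symmetric by
  definition.
* All simulation and sampling functions require an explicit seed and are
  bit-reproducible; published selected-sample sizes are seed-specific and
  reproducible only in distribution, which is why the count checks use
  binomial standard-error bands.

# Known limitations

* Orthant probabilities (hence culling fitness) are implemented for up to
  three culled traits ($T \le 4$).
* The scalar grid posteriors fix the dispersion parameters; unknown-variance
  versions are out of scope.
* The pre-selection model drops the integral over unselected candidates'
  genomic values (it carries no information on the selected ones without
  genotypes, and imputing it from pedigree would be a single-step-style
  extension, deliberately not attempted).
* Multi-kernel REML, fixed-effect design matrices, sparse solvers,
  inbreeding-aware pedigree inverses and multi-generation nor-optimal
  selection are not implemented.
* As the sequential-culling experiment in the test suite reports, the
  culling correction is not guaranteed to reduce error relative to ignoring
  selection — with very few survivors the correction mostly adds
  uncertainty. The package makes the comparison easy rather than promising
  an improvement.
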