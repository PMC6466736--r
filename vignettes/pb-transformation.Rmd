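---
title: "The PB-transformation: testing under correlation and heteroscedasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PB-transformation: testing under correlation and heteroscedasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtrans)
```

## The problem

Many regression-type testing problems in genomics and epidemiology involve
observations that are neither independent nor equally variable: RNA-seq
cohorts mixing matched tumour/normal pairs with unmatched samples,
multi-batch designs, longitudinal measurements. The model is

$$ y = \mathbf{1}\mu + x\beta + \varepsilon, \qquad
   \operatorname{cov}(\varepsilon) = \Sigma = \sigma^2 S, $$

with the null hypothesis $\beta = 0$. A weighted linear mixed model handles
this but is slow and occasionally fails to converge when fitted tens of
thousands of times; naive two-sample tests ignore the correlation (inflating
or collapsing the type-I error), and paired tests discard the unmatched
samples. `pbtrans` takes a third route: a deterministic linear
transformation of the data that makes the classical one-sample tests exact
again.

The scale/shape split is pinned down by the normalization
$\mathbf{1}' S^{-1} \mathbf{1} = 1$ (so
$\sigma^2 = 1/\sum_{ij} (\Sigma^{-1})_{ij}$), which makes the
generalized-least-squares grand mean an unscaled projection
$\hat\mu = \mathbf{1}' S^{-1} y$. `standardize_cov()` performs this split
and every downstream operator assumes it.

## The two maps

**B-map (whitening).** Centering with the weighted mean is the oblique
projection $y^{(1)} = (I - J S^{-1}) y$; its covariance has shape $S - J$
with exactly $n-1$ non-zero eigenvalues. With the eigen-decomposition
$S - J = T \Lambda T'$, the map $B = \Lambda^{1/2} T' S^{-1}$ sends $y$ to
$n - 1$ values with covariance $\sigma^2 I$. With general nuisance
covariates $X_{-k}$ (the multiple-regression extension) the projection is
$C = I - X_{-k} (X_{-k}' S^{-1} X_{-k})^{-1} X_{-k}' S^{-1}$ and the
residual shape is taken as $C S C'$, which reduces to $S - J$ in the
univariate case; `whitening_map()` asserts $B S B' = I$ and $B X_{-k} = 0$
after construction rather than trusting the algebra of any particular
special case.

**P-map (rotation).** The whitened covariate $z = Bx$ carries the signal:
$E(By) = z\beta$. The unique orthogonal matrix
$P = I - QQ' + Q\,\mathrm{Rot}\,Q'$ (from the QR factorization of
$(\mathbf{1}\,|\,z)$, positive-diagonal convention) maps $z$ to
$\zeta \mathbf{1}$ with $\zeta = \lVert z\rVert / \sqrt{n-q}$ while acting
as the identity on the orthogonal complement of $\mathrm{span}(\mathbf 1, z)$.
After both maps, $\tilde y = PBy$ has mean $\zeta\beta\mathbf{1}$ and
covariance $\sigma^2 I$: the original problem is exactly a one-sample
location test, which `pb_ttest()` (Student) or `pb_wilcoxon()` (signed rank,
referred to a t-distribution because the effective sample size can be small)
answers.

Two numerical corners are fixed by convention. Eigenpairs are sorted by
descending eigenvalue and the rank is cut at $10^{-10}$ times the largest
eigenvalue; the discarded null space must have dimension exactly $q$,
otherwise a conditioning error is raised. When $z$ is numerically collinear
with $\mathbf 1$ the QR route degenerates, and $P$ is taken to be the
identity (positive multiple) or the Householder reflection mapping
$z/\lVert z \rVert$ to $\mathbf 1/\sqrt{m}$ (negative multiple). The
eigenvector basis of a degenerate eigenvalue is arbitrary; the audit
quantity $\xi = \langle z, \mathbf 1\rangle /(\sqrt{m}\lVert z\rVert)$
depends on that basis, but the final statistic does not (a property the test
suite checks by flipping eigenvector signs).

## Covariance model and correlation estimation

When $\Sigma$ is not supplied it is built as
$\Sigma = W^{-1/2}\,\mathrm{Cor}\,W^{-1/2}$: $W$ holds per-observation
inverse-variance weights (for RNA-seq, sequencing depth in million reads,
i.e. $w_i = \text{depth}_i \times 10^{-6}$), and $\mathrm{Cor}$ is
block-diagonal compound symmetry, $(1-\rho)I + \rho J$ within each subject
block. Each block matrix is positive definite iff
$\rho \in (\max_l -1/(n_l-1),\, 1)$, and constructors refuse values outside
that interval.

The correlation is estimated from weighted least-squares residuals
$\hat\varepsilon_i = \sqrt{w_i}\,(y - X\hat\beta_W)_i$, whose covariance is
proportional to the block-diagonal correlation. With
$SS_1 = \sum_l \hat\varepsilon_l'\hat\varepsilon_l$ and
$SS_2 = \sum_l (\mathbf 1'\hat\varepsilon_l)^2$,

$$ \hat\rho_{\mathrm m}
   = \frac{SS_2 - SS_1}{\tfrac1n \sum_l n_l(n_l-1)\, SS_1}, $$

which coincides with the maximum-likelihood estimator
$(SS_2-SS_1)/((n_1-1)SS_1)$ for balanced designs. Singleton blocks cancel in
the numerator and are excluded from the block count $L_{\text{used}}$ but
kept in $n$. The downward bias of small-$L$ correlation estimates is
corrected by the Olkin–Pratt factor
$\hat\rho_{\mathrm m}\,[1 + (1-\hat\rho_{\mathrm m}^2)/(2(L_{\text{used}}-3))]$,
applied only when $L_{\text{used}} > 3$ (otherwise the uncorrected estimate
is returned with a warning). Estimates are clamped to
$[\max_l -1/(n_l-1) + 10^{-6},\ 1 - 10^{-6}]$ so the downstream covariance
is always positive definite. The estimator covers only the single
random-intercept exchangeable structure; richer structures (AR(1), random
slopes) are out of scope.

## Effective degrees of freedom

Correlated observations carry less information than independent ones, so
the reference t-distribution needs fewer degrees of freedom than $n - 1 - q$.
`effective_df()` implements a Kenward–Roger-style moment match: the
covariance is written as
$\Sigma(\theta) = \sigma_\varepsilon^2 W^{-1} +
\sigma_\gamma^2 W^{-1/2} Z Z' W^{-1/2}$ with
$\rho = \sigma_\gamma^2/(\sigma_\gamma^2 + \sigma_\varepsilon^2)$ ($Z$ the
block indicator), and the first two moments of the scaled Wald statistic of
the single contrast are matched to an $F(1, \nu)$ via
$\nu = 2 f^2 / (g' \mathcal I^{-1} g)$, where $f$ is the GLS variance of
$\hat\beta_k$, $g$ its gradient in $\theta$ and $\mathcal I$ the expected
REML information. If $\mathcal I$ is singular the match collapses to the
single-variance-parameter (Satterthwaite) version with a warning. Exact
limits, verified in the tests: 40 independent equal-weight samples in two
groups give $\nu = 38$; 20 equal-weight complete pairs give $\nu = 19$ for
any $\rho$; $\nu$ is non-increasing in $\rho$ for a fixed design and never
exceeds $n - 1 - q$. The estimated-$\rho$ tests plug the estimate into the
same machinery without additional inflation.

A useful exact identity: on balanced, perfectly paired, equal-weight data
with the *uncorrected* moment estimate of $\rho$ plugged in, the PB t-test
equals the paired t-test number-for-number (the classic randomized-block
identity); with the oracle $\rho$ or the bias-corrected estimate the
statistic differs slightly in finite samples while keeping the same
distribution. `pb_test(..., correct_rho = FALSE)` exposes the exact-identity
behaviour. For identity-proportional covariance the PB t-test reproduces the
pooled two-sample (more generally, regression) t-test exactly.

## The semiparametric generator

`simulate_response()` inverts the transformation to generate data: from
$n-1$ i.i.d. draws $\check Y$ of any symmetric density scaled to variance
$\sigma^2$, plus one independent draw $Y^*$,

$$ Y = D(\check Y + u\mathbf 1) + (Y^* + v)\mathbf 1, \qquad
   D = T\Lambda^{1/2}P', \quad u = \zeta\beta, \quad
   v = \mu + \beta\,\mathbf 1'S^{-1}x, $$

so that $E(Y) = \mathbf 1\mu + x\beta$ and
$\operatorname{cov}(Y) = \sigma^2 S$ exactly, for the normal,
double-exponential and logistic families (the latter two rescaled to unit
variance before multiplying by $\sigma$). Symmetry of the generating density
is required — the signed-rank test is only valid for symmetric distributions
— and asymmetric requests are rejected. With normal draws the output is
exactly multivariate normal, which makes the generator an independent oracle
for the transformation: noise-free output maps back to $\zeta\beta\mathbf 1$
to machine precision, and Monte-Carlo moments match $(\mathbf 1\mu + x\beta,
\sigma^2 S)$ entrywise.

What the generator does *not* emulate about real RNA-seq data: counts and
their mean–variance relationship (inputs are assumed variance-stabilized,
e.g. log-CPM), gene–gene correlation, outlying samples, and missingness.
Passing tests therefore demonstrate the algebraic and distributional
guarantees of the method, not robustness to preprocessing failures.

## Study conditions used by the harness and tests

`sim_spec()` fixes the simulated conditions once: $n = 40$ observations in
20 subject blocks of size 2; for group comparisons the two group labels are
assigned within each pair, for regression-type tests the covariate is
standard normal; weights are drawn once per replicate from
$\mathrm{Uniform}(0.5, 2)$ and treated as known; $\mu = 1$, $\sigma^2 = 1$;
correlations of interest $\rho \in \{0.2, 0.4, 0.6, 0.8\}$. The default
effect size $\beta = 0.4$ was chosen once to give mid-range power at the
high-correlation setting where the paired structure matters most. Type-I
error is assessed on 2000 null replicates (the binomial 3-SE slack at the 5%
level is then 1.46 points); ROC curves pool null and alternative p-values
over a threshold sweep and AUCs use the trapezoid rule, with between-set
variability reported over 20 contiguous replicate sets. These problem sizes
keep the whole evaluation at desk scale while leaving Monte-Carlo error well
below the margins being asserted.

## High-throughput use

`run_pbtest()` exploits the fact that the composed operator $PB$ depends
only on the design and covariance: it is built once, all features are
transformed in a single matrix product, and the per-feature work after that
is $O(n)$. When no correlation is supplied, a single shared $\rho$ is taken
as the median of the per-feature corrected estimates (a pooling rule chosen
for robustness; the across-feature IQR is logged so a badly heterogeneous
correlation structure is visible). Zero-variance features are dropped and
logged; p-values receive a Benjamini–Hochberg FDR column. Fold-change
filtering is deliberately not part of the test and is left to downstream
code.

## Known limitations

* Only one contrast can be tested per plan; there is no F-type simultaneous
  test, because the rotation has no analogue for a multi-dimensional
  alternative.
* The correlation estimator assumes a common exchangeable $\rho$ across
  blocks.
* The signed-rank variant matches the data only up to second moments for
  non-normal families; its p-values are approximate (though conservative in
  the simulations the package ships).
* With a user-supplied full covariance matrix (no weight/block
  decomposition) the degrees of freedom default to the GLS value $n - p$,
  since no variance-component structure is available to moment-match
  against.
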