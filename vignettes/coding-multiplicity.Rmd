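---
title: "Adjusting for multiple codings of a continuous covariate in GLMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting for multiple codings of a continuous covariate in GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicoding)
```

## The problem

A recurring practice in epidemiology and clinical research: a continuous risk
factor $X$ (a biomarker, an exposure) is entered into a regression model not
as-is but through some transformation — dichotomized at a "clinically
meaningful" cutoff, split into three or four categories, log-transformed,
or expanded as a fractional polynomial. When the right transformation is
unknown, several are tried, and the one with the smallest p-value is
reported. Each trial is a hypothesis test, so the reported p-value is the
minimum of $K$ dependent tests and the nominal type-I error is no longer
controlled. `multicoding` quantifies and corrects this.

## Model and tests

Outcomes $Y_1,\dots,Y_n$ are independent draws from an exponential-family
distribution with canonical parameter modelled, for coding $k$, as
$$\theta_i = \gamma' Z_i + \beta_k' X_i(k), \qquad X_i(k) = g_k(X_i),$$
where $Z_i$ contains the intercept and $q-1$ adjustment covariates and $g_k$
maps $X$ to the coded columns (one column for a dichotomy, Box-Cox transform
or FP1; $m_k - 1$ dummy columns for an $m_k$-class categorization; $m$
columns for an FP of degree $m$). Supported models: gaussian-identity,
binomial-logit, binomial-probit, poisson-log.

Each $H_{0,k}: \beta_k = 0$ is tested with a Rao (efficient) score test
anchored at the *single* null fit $\hat\gamma$ (adjustment covariates only,
fitted by IRLS; the gaussian dispersion is the MLE $\mathrm{RSS}/n$ so the
parametric bootstrap simulates from the null MLE). With
$W = \mathrm{diag}\{(d\mu/d\eta)_i^2 / (V(\hat\mu_i)\, a(\hat\phi))\}$, the
efficient score and its null covariance are
$$U_k = X(k)'\,\mathrm{diag}\Big\{\tfrac{(d\mu/d\eta)_i}{V(\hat\mu_i)\,a(\hat\phi)}\Big\}(y - \hat\mu),
\qquad V_k = \tilde X_k' W \tilde X_k,$$
where $\tilde X_k$ removes the $Z$-directions from $X(k)$ in the $W$ inner
product. One-column codings give the signed statistic
$T_k = U_k/\sqrt{V_k}$ with two-sided normal p-value; multi-column codings
give $Q_k = U_k' V_k^{-1} U_k \sim \chi^2_{m_k-1}$. The *expected*
information is used throughout: it is what makes the joint normal limit of
$(T_1,\dots,T_K)$, and hence the exact correction below, computable in
closed form. Two-sided p-values only; there is no one-sided mode.

The global null $\cap_k H_{0,k}$ is tested by union–intersection: reject
when the smallest $p_k$ (equivalently, for 1-df menus, the largest $|T_k|$)
is small enough, and report as "best coding" the $k$ attaining it (exact
ties go to the first coding in menu order and are flagged).

## The four corrections

**Bonferroni.** $\min(1, K\,p_{\min})$. Conservative under the strong
positive dependence of codings of one variable.

**Exact (maxT).** Under the global null, $(T_1,\dots,T_K)$ for 1-df menus is
asymptotically $N(0, R)$ with
$R_{kl} = \tilde X_k' W \tilde X_l / \sqrt{(\tilde X_k' W \tilde X_k)(\tilde X_l' W \tilde X_l)}$.
The adjusted p-value is
$1 - P(-t_{\max} < Z_k < t_{\max}\ \forall k)$, $Z \sim N(0, R)$, evaluated
by Genz–Bretz quasi-Monte-Carlo integration (`mvtnorm::pmvnorm`, absolute
tolerance $10^{-5}$ by default, the error estimate is reported). The
symmetric rectangle is integrated because the per-test p-values are
two-sided. The method applies only when every coding has one degree of
freedom; menus containing a categorical coding with more than two classes
(or an FP of degree $\ge 2$) get a "not applicable" marker rather than an
error, and the resampling methods below take over.

**Permutation minP.** Under the null and the exchangeability assumption, X
carries no information about $(Y, Z)$, so permuting the X column yields a
valid null replicate. Each of $B$ replicates recomputes all $K$ score tests
and records the minimum p-value $p^{*b}_{\min}$; the adjusted p-value is
$\hat p = B^{-1}\sum_b 1\{p^{*b}_{\min} < p_{\min}\}$ (strict inequality, as
defined; the never-zero estimator $(\#+1)/(B+1)$ is available via
`add_one = TRUE`). Because the null model excludes X, the null fit is
unchanged by permutation and is computed once. Quantile cutoffs are
permutation-invariant and raw cutpoints see the same marginal sample, so
permuting the realized coded rows is identical to re-deriving the codings
per replicate; the implementation does the former. A degenerate-replicate
counter is kept (a replicate would be redrawn), but no permutation replicate
can degenerate for these coding families and tests assert the counter is 0.

**Parametric bootstrap minP.** Outcomes are simulated from the fitted null:
$Y^*_i \sim$ Bernoulli$(\hat\mu_i)$, Poisson$(\hat\mu_i)$ or
$N(\hat\mu_i, \hat\phi)$, keeping X and Z fixed (codings are computed once).
Each replicate re-fits the null on $Y^*$ — the fit genuinely changes here —
and re-runs the $K$ tests. Replicates whose re-fit fails to converge are
redrawn and counted; more than 1% of $B$ failures aborts with a data-quality
error. The same minP estimator is used.

Monte-Carlo standard errors $\sqrt{\hat p(1-\hat p)/B}$ accompany every
resampled p-value. When both resampling methods run in one report, their
seed streams are derived from the single user seed by fixed offsets
(+10^6 permutation, +2·10^6 bootstrap, +3·10^6 for the integration), so one
seed reproduces the whole report bit-identically. A seed is *required*
whenever resampling is requested; there is no silent clock seeding.

## The coding menu

* **Quantiles** are always the type-7 (linear interpolation) sample
  quantile — a convention that had to be fixed once; it is the R default and
  is documented here so reports are reproducible elsewhere.
* **Dichotomies**: $1\{X \ge c\}$; a value exactly at the threshold goes to
  the upper class, and the same boundary convention applies to every
  categorical coding.
* **Automatic menus**: `nb_dicho = n` uses levels $j/(n+1)$ (median,
  terciles, quartiles, ...); `nb_categ = n` builds codings on the terciles
  (3 classes), quartiles (4 classes), quintiles (5 classes), ... The class
  count is always one more than the number of interior cutoffs.
* **Box-Cox**: $\lambda^{-1}(X^\lambda - 1)$, $\log X$ at $\lambda = 0$. The
  same power formula is applied for $\lambda < 0$ (the standard Box-Cox
  form, monotone-equivalent to the reciprocal transforms those exponents
  describe). Non-positive X is a hard error instructing the user to shift —
  an automatic shift would silently change the tested transformation.
* **Fractional polynomials**: columns $H_j$ with $H_0 = 1$, $a_0 = 0$,
  $H_j = X^{(a_j)}$ for a new power and $H_j = H_{j-1}\ln X$ for a repeated
  one, with $X^{(0)} = \ln X$. Powers are sorted on construction (the
  recursion needs $a_1 \le \dots \le a_m$). If $\min(X) \le 0$ the variable
  is shifted by $\zeta = \min(X) - \delta$, with $\delta$ the smallest
  positive gap between distinct sorted values — a data-driven stand-in for
  the lower limit of the measurement's rounding interval — and $\zeta$ is
  recorded in the report; the user may override it.
* **Degenerate codings** (constant column, empty class, tied quantile
  cutoffs) are errors naming the coding, never silent drops: dropping would
  change $K$ and with it every correction.

## What the synthetic generator does and does not emulate

`generate_scenario()` draws independent adjustment covariates (standard
normal or Bernoulli(0.5)), an independent variable of interest (lognormal
by default, so power transforms need no shift; normal or uniform options
exercise the shift path), and outcomes from the requested family. Under
`no_effect()` the outcome depends on Z only, so the global null holds *by
construction* — the basis of all type-I error checks. `threshold_effect()`
injects a step at a quantile of X; `transform_effect()` a smooth effect
through a named coding. `target_mean` calibrates the intercept on the
realized covariates so the marginal prevalence (or rate/mean) hits a target
exactly in expectation — used by `paquid_like_scenario()`, a low-prevalence
(33/311) logistic scenario with four adjustment covariates shaped after a
nested case-control design.

The generator does **not** emulate correlated or longitudinal covariates,
covariate-dependent X, measurement error, or missingness. Passing tests
therefore demonstrate correctness of the procedures under clean sampling
assumptions, not robustness to real-data pathologies; in particular the
permutation method's exchangeability assumption is true by construction
here, while on real data it is an assumption the analyst must own.

## Numerical and design choices

* IRLS convergence: relative coefficient change below `tol` (default 1e-9),
  via the standard weighted-least-squares update; non-convergence and
  rank-deficient adjustment designs are explicit errors naming the problem.
* The score correlation matrix is symmetrized and, if rounding produces a
  negative eigenvalue, clipped to PSD with the diagonal renormalized
  (tolerance 1e-10; a strongly non-PSD matrix triggers a warning since it
  indicates collinear codings).
* `exact_adjust` collapses codings that are perfectly correlated
  ($|r| = 1$ within 1e-12) with an earlier one before integrating: the
  rectangle probability is unchanged and the integrand stays non-singular.
* Default $B = 1000$ balances Monte-Carlo error
  ($\mathrm{SE} \approx 0.007$ at $\hat p = 0.05$) against cost; the strict
  inequality estimator can return exactly 0, which `add_one = TRUE`
  remedies at the price of a $1/(B+1)$ upward bias.

The package's own simulation checks use deliberately moderate problem
sizes — e.g. 500 null replicates at $B = 500$ for the type-I error check
(95% binomial band $0.05 \pm 1.96\sqrt{0.05 \cdot 0.95/500}$), 300
replicates for the power-ordering check, $B = 10{,}000$ for the
cross-method agreement check — chosen so the whole suite runs on a single
CPU in minutes while keeping Monte-Carlo bands tight enough to be
informative.

## Limitations

* Proportional-hazards (Cox) models are not covered; neither are
  quasi-likelihood families, offsets, or user-supplied weights.
* The menu must be declared up front. A data-driven scan over *all* observed
  cutpoints is a different (more extreme) multiplicity problem and is out of
  scope, as are spline codings.
* No step-down (Westfall–Young) procedures, no FDR control, and no
  post-selection confidence intervals for the effect under the chosen
  coding: the selected-coding estimate remains biased away from zero, and
  only the *global* test is corrected here.
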