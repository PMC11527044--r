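---
title: "Highly adaptive lasso regression and targeted causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Highly adaptive lasso regression and targeted causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halcausal)
```

## The estimation problem

Observational studies of a binary treatment observe i.i.d. copies of
$O = (W, A, Y)$: covariates $W \in \mathbb{R}^d$, treatment
$A \in \{0, 1\}$ and an outcome $Y$. Under no unmeasured confounding and
positivity, the average treatment effect (ATE) is the statistical estimand

$$\psi_0 = E_0\left[\bar Q_0(W, 1) - \bar Q_0(W, 0)\right],
\qquad \bar Q_0(W, A) = E_0(Y \mid W, A),$$

and efficient estimation of $\psi_0$ requires estimating the two nuisance
functions $\bar Q_0$ and the propensity $g_0(1 \mid W) = P_0(A = 1 \mid W)$
flexibly *and* fast enough: asymptotic linearity and efficiency of
estimators such as TMLE require the nuisance estimates to converge faster
than $n^{-1/4}$, while remaining in a Donsker class. Parametric models
converge fast but risk misspecification bias; generic machine learning is
flexible but offers neither guarantee.

The highly adaptive lasso (HAL) threads this needle. It is the empirical
risk minimizer over the class of càdlàg (right-continuous with left
limits) functions whose *sectional variation norm* is bounded — a global
smoothness budget rather than a local derivative condition. That class is
Donsker, and HAL attains a dimension-free rate faster than $n^{-1/4}$, so
HAL-fitted nuisances deliver efficient plug-in and TMLE estimators under
assumptions (bounded total variability) that health-science regression
functions essentially always satisfy.

## The HAL model

Any càdlàg function of bounded sectional variation admits a representation
as a (limit of) linear combinations of indicator basis functions
$x \mapsto \mathbf{1}\{x_s \ge u\}$ over coordinate subsets
$s \subseteq \{1, \dots, d\}$ and knots $u$, and its sectional variation
norm equals the $\ell_1$ norm of the coefficients (plus the intercept,
which carries the function value at the lower corner of the domain). HAL
therefore:

1. tabulates knots at every observed data point, for every subset $s$ up
   to a chosen interaction degree (`enumerate_knots()`; up to
   $n(2^d - 1)$ candidate columns, with exact duplicate columns removed);
2. solves the $\ell_1$-constrained least squares / logistic regression on
   this design. We implement the equivalent Lagrangian form
   $$\min_{\beta_0, \beta}\; \frac{1}{n}\sum_i
     L\!\big(Y_i,\, \beta_0 + \Phi(X_i)\beta\big) + \lambda \|\beta\|_1$$
   along a 100-value log-spaced penalty grid spanning
   $[\lambda_{\max} \cdot 10^{-4}, \lambda_{\max}]$, with the intercept
   unpenalized, and report the achieved $|\beta_0| + \|\beta\|_1$ as the
   variation-norm bound (`fit_hal()`). `fit_hal_bounded()` additionally
   cross-validates directly over a grid of norm bounds $M$, matching the
   constrained formulation through path equivalence.

Two conventions matter and are fixed deliberately:

* indicators are closed at the knot, $\mathbf{1}\{x \ge u\}$, so
  zeroth-order fits are right-continuous step functions — càdlàg by
  construction;
* design columns are **never standardized**: rescaling indicator columns
  would break the identity between the coefficient $\ell_1$ norm and the
  sectional variation norm.

First-order bases replace indicators by hinges $\max(x - u, 0)$
(`order = 1`); higher spline orders are not implemented.

The penalty is selected by V-fold cross-validation (default $V = 10$,
deterministic fold assignment from a seed), minimizing mean validation
risk with ties resolved to the larger penalty. Per-column penalty factors
allow bases that are known a priori to belong in the model to enter
unpenalized (`penalty_factor = 0`).

### Knot reduction

The canonical dictionary grows as $n(2^d - 1)$. When the candidate column
count exceeds `column_budget` (default $10^5$), `knot_reduction = "auto"`
falls back to per-coordinate empirical quantile knots (`"quantiles"`,
$m$ per coordinate before tensor products); `"kmeans"` instead places
$m$ centroid knots per subset. These are fidelity/cost dials: fewer knots
coarsen the sieve and add approximation bias but leave the methodology
unchanged.

## Causal estimators

With HAL nuisances $\bar Q_n, g_n$ the package provides:

* **Plug-in (g-computation)** `plugin_ate()`:
  $\psi_n = \frac1n \sum_i [\bar Q_n(W_i, 1) - \bar Q_n(W_i, 0)]$. Valid
  efficient inference for the raw plug-in requires *undersmoothing*:
  `undersmooth_select()` walks the penalty path from the CV choice toward
  weaker penalties until the empirical mean of the target score
  (the efficient influence curve for the ATE) satisfies
  $|P_n D^\star| \le \sigma_n / (\sqrt{n}\,\log n)$ — the MLE-like regime
  in which the fit solves the relevant score equation. When no grid point
  meets the criterion, the smallest penalty is returned with
  `achieved = FALSE`; callers should treat that flag seriously — a fully
  undersmoothed propensity at small samples can memorize the treatment
  labels, and the command-line `tmle --undersmooth-g` therefore falls back
  to the cross-validated penalty in that case.
* **IPTW** `iptw_ate()`:
  $\psi_n = \frac1n\sum_i [A_i Y_i / g_n(1|W_i) - (1-A_i) Y_i / g_n(0|W_i)]$,
  with optional undersmoothing of the propensity along its path using the
  same criterion.
* **TMLE** `tmle_ate()`: updates $\bar Q_n$ along the logistic fluctuation
  $\operatorname{logit} \bar Q^\star = \operatorname{logit} \bar Q_n +
  \varepsilon H$ with clever covariate
  $H(A, W) = A/g_n(1|W) - (1-A)/g_n(0|W)$, $\varepsilon$ fitted by maximum
  likelihood. At the MLE the score $\sum_i H_i (Y_i - \bar Q^\star_i) = 0$,
  so the TMLE solves the efficient-influence-curve equation
  $P_n D^\star = 0$ exactly (numerically, below $10^{-8}$), and the Wald
  interval $\psi_n \pm z_{1-\alpha/2}\, \widehat{sd}(D^\star)/\sqrt n$ is
  asymptotically efficient. Being a substitution estimator, the TMLE
  respects global bounds: for binary outcomes the estimate cannot leave
  $[-1, 1]$.

Continuous outcomes are affinely mapped to $[0, 1]$ for the fluctuation
(bounds = observed range by default, configurable) and mapped back.
Predicted propensities are truncated to `g_bounds` (default
$[0.005, 0.995]$) with truncation counts reported in the diagnostics.
`eic_ate()` exposes the canonical gradient itself and
`exact_remainder_ate()` the second-order remainder
$R_2 = E_0[\frac{g_0 - g_n}{g_n}(1|W)(\bar Q_0 - \bar Q_n)(W,1) -
\frac{g_0 - g_n}{g_n}(0|W)(\bar Q_0 - \bar Q_n)(W,0)]$ for simulation
analysis with known truths.

### Fluctuation numerics

$\varepsilon$ is fitted by a damped Newton iteration on the score
(fallback: bracketed root finding on $[-20, 20]$), stopping at
$|\text{score}| < 10^{-11} n$. This guarantees the empirical
influence-curve equation is solved to $10^{-8}$ even where an offset-GLM's
default deviance-based stopping rule would not.

## Bootstrap inference with plateau selection

Wald intervals can undercover in finite samples when the second-order
remainder is non-negligible. `bootstrap_ci_path()` implements the
nonparametric bootstrap along the penalty path: for each penalty
$\lambda$ whose fit has variation norm at least the CV-selected norm, it
draws $B$ row resamples, refits HAL at $\lambda$ (support re-selected
within each resample), refits the relaxed (unpenalized) regression on the
selected support, reruns the TMLE targeting step, and forms an interval
from the bootstrap spread (normal-approximation by default, percentile
optional). Resamples with a single treatment arm are redrawn (capped at
$10B$). Interval widths grow as $\lambda$ decreases and flatten once the
fit tracks the target function; `plateau_select()` locates the plateau
onset at the grid point of extremal discrete second difference of the
width sequence. The second-difference operator is applied to the raw
widths by default — a 3-point moving-average smoother is available via
`window = 3` — with ties resolved toward the larger penalty, and a flat
or exactly linear width curve returns the largest penalty with a warning.
The selector is scale-equivariant by construction. Within each bootstrap
replicate the original knot dictionary is evaluated on the resampled rows;
since a resample's observed points are a subset of the original sample,
this dictionary contains every knot the resample itself would generate.

## Working-model inference for CATE and dose-response

The relaxed HAL fit defines a data-adaptively selected finite-dimensional
working model. Treating its support as fixed, classical delta-method
inference applies: `working_model_covariance()` returns the
heteroscedasticity-robust (HC0 sandwich) covariance of the unpenalized
coefficients, and

* `cate_curve()` evaluates $\tau(w) = \bar Q(w, 1) - \bar Q(w, 0) =
  c(w)^\top \beta$,
* `dose_response_curve()` evaluates $\theta(a) = \frac1n \sum_i
  \bar Q(W_i, a) = \bar c(a)^\top \beta$ for continuous treatments,

each with pointwise delta-method intervals
$\pm z \sqrt{c^\top \hat\Sigma c}$ and a simultaneous band calibrated by
the $1-\alpha$ quantile of the maximum absolute standardized Gaussian
draw over the evaluation grid ($10^4$ seeded draws from the implied
covariance; the band multiplier is floored at the pointwise $z$, so the
band always contains the pointwise interval). The covariance conditions
on the selected support: this post-selection approximation is exactly
what makes the working-model view tractable, and it is the main caveat —
the bands do not account for support-selection variability.

## Synthetic data with known truth

`gen_sinusoid(n, seed)` reproduces the univariate test bed
$X \sim U(-4, 4)$, $Y = 2\sin(\tfrac{\pi}{2}|X|) + N(0, 1)$, whose true
regression function has sectional variation norm exactly 16 on $[-4, 4]$
(verifiable with the quadrature-style oracle `true_variation_norm_1d()`).
`gen_ate_dgp()` draws from registered causal scenarios, each with
closed-form truth attached:

* `"linear"`: $W \sim U(0,1)^2$,
  $g_0(1|W) = \operatorname{expit}(2(W_1 - 0.5))$,
  $\bar Q_0(W, A) = 0.2 + W_1 + 0.5 W_2 + (a_0 + a_1 W_1) A$ with noise
  sd $\sigma = 0.5$ and defaults $a_0 = 0.5$, $a_1 = 0$, so
  $\psi_0 = a_0 + a_1/2$. The moderate propensity slope keeps
  $g_0 \in [0.27, 0.73]$ — a realistic, positivity-respecting
  observational design; $\sigma = 0.5$ gives a signal-to-noise ratio at
  which $n = 500$ is informative but not trivial.
* `"null"`: treatment depends on $W_1$, the outcome only on $W_2$, so
  $Y \perp A$ and $\psi_0 = 0$.
* `"near_positivity"`:
  $g_0(1|W) = 0.001 + 0.999\,\operatorname{expit}(8(W_1 - 0.8))$, which
  ranges through $[0.001, 0.02]$ on roughly the lower third of the
  $W_1$ axis — a practical positivity violation for stress-testing
  truncation and weight diagnostics.
* `"binary"`: $\bar Q_0(W, A) = \operatorname{expit}(-0.5 + W_1 + A)$,
  Bernoulli outcomes, $\psi_0$ computed by one-dimensional quadrature.

Every generator draws from a local seeded RNG stream (identical inputs
give identical datasets; the caller's RNG state is untouched). These
scenarios emulate low-dimensional, additive, homoscedastic designs with
uniform covariates; they do not exercise high-dimensional covariates,
heavy-tailed noise, informative missingness, or measurement error, so
passing tests certify correctness of the estimators under the stated
models, not robustness to everything real data can do.

## Numerical choices and degenerate inputs

* glmnet solves the penalized problem with `standardize = FALSE`,
  convergence threshold $10^{-7}$ and an iteration cap of $10^5$;
  tiny-instance tests verify the solution against an independent
  proximal-gradient oracle to $10^{-6}$ relative objective error.
* Duplicate design columns keep the lexicographically smallest
  $(s, u)$ term, making dictionary construction deterministic.
* Exactly collinear columns in relaxed refits are dropped (first kept)
  with a warning; rank-deficient working models are pruned likewise.
* A constant binomial outcome yields an intercept-only fit with a
  warning rather than an error.
* Degenerate (zero-variance) influence curves produce zero-width Wald
  intervals with a warning.
* When fewer than four path points lie at or below the CV penalty (e.g.
  noiseless data), the bootstrap grid pads upward with larger penalties
  so the plateau search remains defined.

## Problem sizes used in the test suite

The simulation-based checks run at deliberately modest scale, chosen as
the package's own trade-off between Monte-Carlo resolution and a test
suite that runs in minutes: Wald coverage of HAL-TMLE over 200
replications at $n = 500$ (nuisances fit additively with 10 quantile
knots per coordinate, 5-fold CV, 50-value penalty grid); the
bootstrap-versus-Wald width and coverage comparison over the first 40 of
those replications at $B = 200$ with an 8-penalty grid; the TMLE score
equation over 100 datasets at $n = 150$; solver-versus-oracle equivalence
over 50 random tiny instances ($n \le 20$). The sinusoid variation-norm
experiment uses the full design ($n = 500$, all observed knots, ten-fold
CV over 100 candidate bounds on $[0, 350]$).

## Limitations

* Spline orders $k \ge 2$, monotonicity-constrained fits, super-learner
  ensembling, conditional-density losses, cross-fitted (CV-)TMLE and
  trial-augmentation estimands are out of scope.
* Working-model inference conditions on the selected support
  (post-selection approximation).
* The canonical knot dictionary scales as $n(2^d - 1)$; beyond the column
  budget the quantile/k-means reductions trade approximation fidelity for
  tractability.
* Undersmoothing inherits the score-equation reading
  $\sigma_n / (\sqrt n \log n)$ of the selection level; the threshold
  constant is exposed rather than hidden.
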