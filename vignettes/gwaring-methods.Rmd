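---
title: "Methods: the generalized Waring regression model in gwaring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the generalized Waring regression model in gwaring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaring)
```

## The model and its assumptions

The generalized Waring regression model (GWRM) assumes that a count
response $Y$ given covariates $x$ follows the univariate generalized
Waring distribution $UGWD(a_x, k, \rho)$, the beta-negative-binomial
distribution generated by the hierarchy

* $Y \mid \lambda \sim \mathrm{Poisson}(\lambda)$ — pure chance
  ("randomness");
* $\lambda \mid v \sim \Gamma(a_x, \text{scale} = v)$ — differing
  exposures to risk ("liability", tied to the covariates through $a_x$);
* $v \sim \mathrm{BetaII}(\rho, k)$ — a stable individual propensity
  independent of the covariates ("proneness").

The mean is $\mu_x = a_x k/(\rho - 1)$, modelled log-linearly as
$\mu_x = e^{x'\beta}$ so that $a_x = \mu_x(\rho - 1)/k$; an `offset()`
term enters the linear predictor with coefficient 1 and acts as an
exposure. The mean exists for $\rho > 1$ and the variance for
$\rho > 2$, in which case

$$\mathrm{Var}(Y \mid x) = \mu_x + \frac{k+1}{\rho-2}\mu_x +
\mu_x^2\frac{k+\rho-1}{k(\rho-2)},$$

the three terms being the randomness, liability and proneness components
reported by `partvar()`. Because the components other than randomness
grow differently with $\mu_x$, the proportions shift with the mean: for
fixed $(k, \rho)$ the randomness share decreases and the proneness share
increases as $\mu_x$ grows. The model nests the usual negative binomial
regressions as limits (NegbinI as $k = \rho \to \infty$ together,
NegbinII as $\rho \to \infty$ with $\mu_x/k$ bounded) and has a
power-law tail $f(y) \sim C y^{-(\rho+1)}$, so very large counts are far
more probable than under Poisson or negative binomial models.

A note on conventions: some renderings of the model's mean drop the $k$
factor ($\mu_x = a_x/(\rho-1)$). This package uses
$\mu_x = a_x k/(\rho-1)$, i.e. $a_x = \mu_x(\rho-1)/k$, the reading
under which the published worked-example variance partitions are
reproduced exactly; the distribution itself is symmetric in $(a, k)$, so
the convention only fixes which factor carries the covariates.

## Numerical treatment of the mass function

All probability mass work is done in log space. The log-mass is
assembled from `lbeta()` terms whose magnitudes stay of order
$(a + k + \rho)\log y$ rather than differences of large `lgamma()`
values, which removes the catastrophic cancellation that otherwise
appears when the optimizer explores large $\rho$ or large means; the
closed-form case $UGWD(1,1,2)$, $f(y) = 4/((y+1)(y+2)(y+3))$, is
reproduced to better than $10^{-12}$ relative error over
$y \in [0, 10^3]$. The $(a, k)$ pair is sorted before evaluation so the
analytic $a \leftrightarrow k$ symmetry holds bit-exactly. Inside the
likelihood two guards reject pathological regions instead of returning
noise: linear predictors above 25 (means beyond $e^{25}$ are
meaningless for count data and overflow the gamma arguments), and any
pointwise log-probability above $+10^{-6}$ (a log-probability cannot be
positive, so positives are rounding garbage; the optimizer then sees a
large penalty rather than an artificial optimum).

## Fitting strategy and its tunable parameters

`gw()` maximizes the weighted log-likelihood in three stages:

1. Newton-type minimization (`nlm`) on $(\beta, k_0, \rho_0)$ with
   $k = e^{k_0}$, $\rho = 1 + e^{\rho_0}$ — unconstrained, and the
   reparameterization guarantees the fitted mean exists;
2. Nelder–Mead simplex on the same scale, started from stage 1's
   solution;
3. bounded quasi-Newton (`L-BFGS-B`) on the natural scale
   $(\beta, k, \rho)$ with bounds $k \ge 10^{-5}$,
   $\rho \ge 1 + 10^{-5}$, started from the better of stages 1–2.

Standard errors for every parameter, including $k$ and $\rho$, come from
the inverse numeric Hessian of stage 3; when `method` selects a single
log-scale optimizer, standard errors are available only for
$(\beta, k_0, \rho_0)$ and no delta-method back-transform is attempted.
An analytic gradient (digamma differences, chained through
$a_x = \mu_x(\rho-1)/k$) is supplied to stages 1 and 3; it matches
central finite differences to $10^{-4}$ relative in the tests.

Defaults, overridable through `gw_control()` and the `gw()` arguments:
`kstart = 1`, `rostart = 2` (dimensionless dispersion starting values),
`betastart` from a Poisson log-linear fit (the standard stable
initialization for the mean model), gradient tolerance $10^{-6}$, at
most 500 iterations per stage, stage-3 bound offsets $10^{-5}$. The
convergence code reported is that of the final stage; ties between the
stage-1 and stage-2 solutions are broken by the smaller objective value.
Case weights multiply log-likelihood contributions; the $n$ in the BIC
penalty $\ln(n)\cdot\text{npar}$ is the number of rows used after
listwise deletion of missing values (which is logged, never silent).

## Inference

`summary()` reports Wald $z = \hat\theta/\mathrm{SE}$ with two-sided
normal p-values for the regression coefficients; the dispersion pair is
reported without p-values (testing $k$ or $\rho$ against a boundary is
not a Wald-regular problem). `lrt()` compares nested fits by
$2(\ell_1 - \ell_0)$ against $\chi^2$. `add1()`/`drop1()` refit one
candidate term at a time (failed refits are flagged in the table, not
dropped), and `step_gw()` performs greedy stepwise search under AIC or
BIC; under `direction = "both"` every addition and deletion is
re-evaluated at every round, and criterion ties within $10^{-8}$ go to
the smaller model so the search is deterministic. `partvar()` refuses
$\hat\rho \le 2$ (infinite variance) and warns for
$\hat\rho \in (2, 2.001]$, where the partition is numerically fragile.

## Residuals and the simulated envelope

Response residuals are $y_i - \hat\mu_i$; Pearson residuals divide by
the square root of the three-component variance (requiring
$\hat\rho > 2$); deviance residuals are
$\mathrm{sign}(y_i-\hat\mu_i)\sqrt{d_i}$ with
$d_i = 2[\ln f(y_i \mid \mu = y_i) - \ln f(y_i \mid \mu = \hat\mu_i)]$
holding $(\hat k, \hat\rho)$ fixed. Two degeneracies are handled
explicitly. At $y_i = 0$ the saturated term uses the limit
$\mu \to 0^+$, under which the mass at zero tends to 1 and the term to
0. And because the UGWD is not an exponential family in $\mu$, $\mu = y$
is not exactly the per-observation likelihood maximizer, so $d_i$ can be
marginally negative when $\hat\mu_i$ is very close to $y_i$; such values
are clamped to zero before the square root (they are of order
$10^{-2}$ at most and correspond to residuals that are essentially
zero).

The envelope simulates `rep` response vectors from the fitted model at
the observed covariates, *refits* the model to each (so the band
reflects estimation noise, not just sampling noise), sorts each
replicate's residuals, and takes the per-rank minimum and maximum. With
min/max bounds and `rep = 19`, the largest absolute residual of
correctly specified data falls outside the band with probability exactly
$1/20$ — the construction that makes the conventional "1 in 20" reading
exact, which is why min/max is used rather than percentiles. Replicate
refits use the bounded quasi-Newton stage warm-started at the original
estimates (the replicates are draws from that very model, so the warm
start is reliable and fast). Each replicate derives its own seed from
the envelope seed, making the result bit-identical whether computed
serially or with forked workers, and making envelopes with larger `rep`
under the same seed nest the smaller ones; a replicate whose refit fails
is re-simulated under the next derived seed, at most three times.
Ordered signed residuals are plotted against normal order statistics
(`qnorm(ppoints(n))`).

## The synthetic-data generator

`gw_simulate()` draws covariates from a declared profile, forms
$\mu_i = e^{x_i'\beta + \text{offset}_i}$, and samples
$y_i \sim UGWD(\mu_i(\rho-1)/k, k, \rho)$ by the exact two-stage
beta-negative-binomial route ($p \sim \mathrm{Beta}(\rho, k)$,
$Y \sim \mathrm{NB}(a, p)$) — no rejection step, and validated in the
tests against the three-stage Poisson–gamma–beta-prime hierarchy
(`rugwd_latent()`, with $v = (1-p)/p$ realized as a ratio of gamma
draws, the beta-prime construction whose marginal matches the mass
function; shape-order conventions for BetaII vary, so agreement is
established by test rather than assumed from a convention). Every
generated table carries a truth record with all parameters and the seed.

Two fixtures emulate the shapes of the model's classical applications.
`badhealth_like` mimics a health-survey table: bad-health prevalence
0.11 (the approximate prevalence in the original survey), integer age
uniform on 20–60 with a true coefficient of zero (age is retained so
that selection procedures have a plausible null covariate to reject),
and truth $\beta = (0.66, 1.16, 0)$, $k = 1.57$, $\rho = 6.85$ —
values inspired by published estimates for data of this shape but to be
read as arbitrary defaults, not as ground truth about any real survey.
`goals_like` mimics a goals-by-position table: a 3-level position factor
with reference `"defender"`, an exposure `Matches` uniform on 1–38
entering as a log offset, and truth $\beta = (-3.8, 0.9, 2.0)$,
$k = 1.2$, $\rho = 4$, chosen to give defender scoring rates of about
0.02 goals per match with strong overdispersion. What these fixtures do
*not* emulate — and hence what passing tests do not demonstrate about
real data — includes covariate measurement error, misspecified link or
omitted covariates, zero-inflation beyond what the UGWD itself implies,
and the season-to-season dependence of repeated-measurement designs.

## Problem sizes used by the test suite

The suite exercises parameter recovery on one fixed-seed dataset of
$n = 5000$ (each estimate within three reported standard errors of
truth) and estimates coefficient bias over 100 replicates of $n = 2000$;
the envelope's extreme-residual escape rate is measured over 100 outer
replicates of $n = 300$ with `rep = 19`; the likelihood-ratio test's
size is measured over 200 replicates of $n = 2000$ with a truly null
covariate. These sizes were chosen to give Monte-Carlo error small
enough for the stated checks while keeping a full test run at desk
scale. Replicated studies use the single-stage bounded quasi-Newton
fitter; the full three-stage strategy is exercised on the fixed-seed
fits.

## Known limitations

* The dispersion pair $(k, \rho)$ is weakly identified at moderate
  sample sizes — standard errors for $\rho$ of the same order as the
  estimate are common below a few thousand observations. The mean model
  is unaffected; interpret the variance partition with the reported
  uncertainty in mind.
* When $\hat\rho \le 2$ the model asserts infinite variance: Pearson
  residuals and the variance partition are deliberately unavailable
  rather than approximated.
* The formula interface supports additive terms, factor dummy coding
  and a log offset; interactions and smooth terms are out of scope.
* Case weights are likelihood weights; the BIC sample size is the row
  count, so frequency-weight semantics require expanding rows.
* The likelihood surface can be multimodal in $(k, \rho)$ for small
  $n$; the three-stage strategy with a simplex stage is a mitigation,
  not a guarantee. Refitting from other `kstart`/`rostart` values is
  cheap and recommended when an estimate sits on a bound.
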