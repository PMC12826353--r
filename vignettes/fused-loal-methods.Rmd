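---
title: "Adaptive selection and fusion of longitudinal treatment models"
author: "loalfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive selection and fusion of longitudinal treatment models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loalfuse)
```

## The estimation problem

With a time-varying binary treatment $A_t$, $t = 0, \dots, T$, covariates
$L_t$ measured before each $A_t$, and a continuous end-of-study outcome $Y$,
the target is the marginal structural model (MSM)

$$\mathbb{E}(Y^{\bar a} \mid L_{01}) = \mu_0 + \mu_1 L_{01} + \mu_2\,
\mathrm{cum}(\bar a),$$

where $Y^{\bar a}$ is the potential outcome under the forced treatment
pattern $\bar a = (a_0, \dots, a_T)$, $L_{01}$ is a single baseline
covariate, and $\mathrm{cum}(\bar a)$ counts treated time points. Under
sequential exchangeability, positivity, and consistency, $\mu$ is identified
through the backwards recursion
$q_t(\bar a, \bar L_t) = \mathbb{E}\{q_{t+1} \mid \bar A_t = \bar a_t, \bar
L_t\}$ initialized at $q_{T+1} = Y$, and can be estimated either by
sequential g-computation (`msm_gcomp()`) or by inverse probability of
treatment weighting (`msm_iptw()`) with stabilized weights
$w = \prod_t g_t(a_t \mid L_{01}) / g_t(a_t \mid \bar L_t, \bar A_{t-1})$.

IPTW hinges on the treatment models $g_t$. A "saturated" specification —
one logistic model per time, conditioning on the full covariate and
treatment history — is robust but noisy: it adjusts for instruments
(covariates that affect only treatment), which is known to inflate the
variance of weighted estimators, and it spends a separate parameter on
every covariate-by-time combination. The package implements a two-step,
data-adaptive reduction of this saturated pooled model.

## Step one: outcome-adaptive selection

The pooled treatment model stacks the per-time logistic models via indicator
interactions (`build_pooled_design()`): each row is a (subject, time) pair,
each time block has its own intercept indicator, covariate-history columns
$\mathbb{I}(\text{time} = \tau) L_{t,k}$ for $t \le \tau$, and
past-treatment columns. There is no global intercept. Per-time intercepts
and past-treatment coefficients are never penalized.

Whether a covariate belongs in the model is judged by its relation to the
*outcome*, not the treatment. Working structural models are fit by stacking
the estimated $q_t^{\bar a}$ over all patterns and regressing on the
covariate history and the pattern's past treatments
(`fit_q_sequence()`, `working_beta()`); their coefficients $\hat\beta$
converge to zero precisely for covariates with no conditional outcome
association. The selection step solves a weighted-$L_1$ penalized pooled
logistic regression,

$$\hat\alpha(\lambda) = \arg\min_\alpha\; -\ell(\alpha) + \lambda
\sum_{j \in \mathcal{J}} \hat\omega_j |\alpha_j|, \qquad
\hat\omega_j = |\hat\beta_j|^{-\gamma},$$

so instruments (tiny $|\hat\beta|$) are penalized enormously while strong
outcome predictors pass almost free. The exponent must satisfy
$\gamma > 2$ for the selection-consistency rate conditions; the default is
$\gamma = 2.5$. An exactly zero $\hat\beta_j$ receives the finite cap
$10^{12}$ rather than an infinite weight, which keeps the objective finite
while excluding the coefficient for any practical $\lambda$.

The solver (`fit_loal_path()`) is an IRLS outer loop with cyclic
coordinate-descent soft-thresholding inside, warm-started along a
descending grid of 30 $\lambda$ values log-spaced from the smallest
all-zero $\lambda$ (computed from the subgradient bound at the null model)
down to $10^{-4}$ times it. Convergence is declared at a coefficient
max-change below $10^{-9}$, which in practice yields per-observation KKT
residuals below $10^{-6}$; every reported solution carries its residual.
An equivalent column-rescaling implementation (divide column $j$ by
$\hat\omega_j$, apply a plain LASSO, rescale back) passes the same KKT
certificates; the explicit-weight form was kept because it makes the
weight cap and the unpenalized slots visible in one place.

### Tuning by longitudinal balance

$\lambda$ is *not* tuned by prediction loss — the goal of the treatment
model is covariate balance, not fit. For each candidate $\lambda$ the
package computes a longitudinal weighted absolute mean difference
(`balance_score()`): at each time $\tau$, the absolute difference in
stabilized-IPT-weighted covariate means between treated and untreated,
weighted by the covariate's $|\hat\beta|$ and summed over covariates and
times, with equal weight across times. The numerator of the balance weights
uses marginal per-time treatment frequencies; stabilization cancels in the
weighted-mean ratios but improves the numerics of the cumulative products.
The exact functional form of this longitudinal metric was an open design
point; this reconstruction extends the established single-time-point
weighted-absolute-mean-difference criterion one dimension at a time and is
isolated in a single function so an alternative summary can be swapped in.
Ties select the largest $\lambda$ (the most parsimonious model), and any
$\lambda$ whose fitted probabilities hit 0/1 numerically is infeasible.
A deterministic alternative $\lambda_n = n^{\aleph}$, $\aleph < 0.5$, is
available via `lambda_rule = "n_power"` for users who prefer a tuning-free
rule; the balance criterion remains the default because it adapts to the
realized covariate distribution.

After selection, the active model is refit by unpenalized maximum
likelihood (`select_lambda_and_refit()`); all downstream weighting uses the
refit. With a censoring process the identical machinery runs on the
censoring indicators (`process = "censoring"`, always treated as
absorbing), and a joint selection rule minimizes the *sum* of the treatment
and censoring balance metrics over a shared grid index.

## Step two: adaptive fusion across time

Even the selected model may spend several parameters on one covariate whose
association with treatment is stable over time. The fusion step ties such
coefficients together. A graph (`build_fusion_graph()`) declares which
coefficients may fuse: coefficients of the same once-measured covariate
across model times (all pairs for a `"clique"` family, successive times for
`"chain"`), and coefficients of repeated measurements of one series at
equal lag $\tau - t$ (declared via `series=`). The fitted criterion is

$$\arg\min_{\alpha^*} -\ell(\alpha^*) + \lambda_1 \sum_{(u,v) \in E}
\frac{|\alpha^*_u - \alpha^*_v|}
{|\hat\alpha^{\text{refit}}_u - \hat\alpha^{\text{refit}}_v|^{\gamma_1}},$$

with *no* magnitude penalty: selection already happened, and the two steps
have different statistical goals (balance versus model simplification), so
the zero pattern of step one is preserved exactly. The default
$\gamma_1 = 2.5$; any positive value is admissible and a small grid can be
searched.

The solver is an IRLS outer loop around an exact solver of the weighted
quadratic fused problem: coordinate moves over current fusion groups (each
a one-dimensional piecewise-quadratic minimization with breakpoints at
neighboring coefficient values), merge moves when two connected groups
meet, and an enumeration-based split check at convergence so that a group
is never left fused when splitting any subset would lower the objective
(groups beyond 16 nodes skip the exhaustive check with a warning; fusion
groups in practice hold a handful of coefficients). On small instances the
solution matches brute-force minimization of the penalized objective to
machine precision.

### Fusion as a discrete structure, tuned by BIC

Fusion is made discrete: after solving at each $\lambda_1$, coefficients
within $10^{-6}(1 + |\alpha^*_u|)$ across an edge are snapped by refitting
the model with the fused columns summed, which is exactly the
shared-parameter maximum likelihood fit for that partition. The
$(\gamma_1, \lambda_1)$ grid is therefore a device for generating candidate
partitions; candidates are compared by
$\mathrm{BIC} = -2\,\ell_{\text{refit}} + \mathrm{df}\,\log N$ with
$N$ the pooled row count and $\mathrm{df}$ the number of distinct
coefficient values among graph nodes plus the remaining free parameters
(the degrees-of-freedom convention standard for fused-LASSO paths; the
methodology leaves it open, and counting distinct values makes the
comparison exact rather than dependent on solver shrinkage). Ties prefer
the more fused structure. For a single fusible pair with truly equal
coefficients this reproduces the classical behavior: fusion is rejected
only when twice the log-likelihood difference exceeds $\log N$, an event
of probability $\approx 1\%$ at $N = 1000$ — which is what the
oracle-weighted fusion experiment in the test suite measures.

The $\lambda_1$ grid is $\{0\}$ plus 20 log-spaced points whose upper end
is doubled until the whole graph fuses, so both extremes (no fusion, full
fusion) are always candidates.

## The synthetic data generator

`dgp_spec()` describes a sequential structural equation model: Gaussian
covariates with linear (or polynomial, via `lp_term()`) means over history,
logistic treatment assignment, and a Gaussian outcome. `scenario1_spec()`
is the built-in two-time benchmark: $C_0, I_0 \sim N(0,1)$;
$A_0 \sim \text{Bern}(\text{expit}(1.515 C_0 + I_0))$;
$C_1 \sim N(A_0 + C_0, 1)$; $I_1 \sim N(C_0, 1)$;
$A_1 \sim \text{Bern}(\text{expit}(-0.5 + 0.5 C_0 + 0.25 C_1 + 0.5 A_0 +
I_1))$. The treatment coefficients are calibrated so that the
instrument-free marginal models carry the *same* coefficient 1.28 on $C_0$
at both times — so the correct adaptive behavior is to select
$\{C_0\}$ and $\{C_0, C_1\}$ and then fuse the two $C_0$ coefficients.
Covariates are standardized to sample mean zero and unit sample standard
deviation after generation (mirroring applied practice; the constants are
recorded), treatments and outcome are not.

Three outcome variants exercise the selection machinery under correct and
misspecified working models: main terms in $(C_0, A_0, C_1, A_1)$; an
added $C_0 C_1$ covariate interaction; an added $A_0 C_1^2$
effect-modification term. The noise standard deviations (all 1) and the
default outcome coefficients ($0.5, 0.75, 1, 1.25$ on $C_0, A_0, C_1, A_1$;
$0.5$ on the variant's extra term) are package choices — selected once so
that confounders carry clearly nonzero working-model coefficients while
instruments do not — and both are overridable. They are not taken from any
external source. With these defaults the implied working-model
coefficients are approximately $1.5$ ($C_0$, time 0), $0.5$ ($C_0$,
time 1), and $1.6$ ($C_1$), so the time-1 $C_0$ coefficient is the hardest
selection and behaves accordingly at small $n$.

What the generator does *not* emulate: nonlinear or non-Gaussian covariate
processes, informative visit times, time-to-event outcomes, and real-world
missingness patterns. Passing tests on these processes demonstrate
correctness of the estimating machinery under its stated assumptions, not
robustness to violations of them.

`true_msm_parameters()` evaluates the true $\mu$ by forcing each treatment
pattern in the structural equations and projecting the counterfactual
outcomes onto the MSM by stacked least squares. The exogenous noise draws
are shared across patterns (common random numbers), which is valid because
a pattern only changes the forced treatment values, and reduces Monte-Carlo
variance substantially.

## The simulation harness and problem sizes

`run_experiment()` replicates: generate, estimate with every configured
estimator (sequential g-computation; full IPTW; selection and
selection-plus-fusion oracles; LOAL; fused LOAL), and aggregate
$n \times |\text{bias}|$ and $n \times \text{MSE}$ against the true $\mu$,
plus selection and fusion proportions, all with Monte-Carlo standard
errors. Because the published-style tables are ambiguous about whether the
bias cell scales the absolute mean error or the mean absolute error, both
are reported (`n_abs_bias`, `n_mean_abs_bias`). Failed replications are
recorded and excluded rather than crashing the run. Replication seeds are
derived reproducibly from one base seed, so a results table is a pure
function of its configuration.

Default problem sizes are desk-scale choices: 200 replications (with MC
standard errors always attached so the noise is quantified), sample sizes
$\{200, 500, 1000\}$, and $2 \times 10^5$ Monte-Carlo draws for the true
parameters. The stacked working-model regressions weight every pattern
replicate equally; plausibility weighting of patterns is a possible
refinement the methodology leaves open.

## Numerical choices and degenerate inputs

* Penalized-logistic convergence: coefficient max-change $< 10^{-9}$,
  IRLS weights floored at $10^{-6}$, at most $10^4$ iterations, failure
  raises an error carrying the $\lambda$ index. Coefficients beyond 100 in
  absolute value trigger a separation warning.
* Fused solver: outer tolerance $10^{-8}$, merge tolerance $10^{-9}$,
  snap tolerance $10^{-6}(1+|\alpha|)$, split checks exhaustive to 16-node
  groups.
* Weight caps: $|\hat\beta| = 0$ or exactly-equal refit coefficients cap
  the corresponding adaptive weight at $10^{12}$ with a warning.
* Positivity: fitted probabilities within $10^{-10}$ of 0/1 invalidate a
  balance evaluation; weight denominators below $10^{-12}$ raise an error
  naming the offending subjects.
* Rank deficiency: aliased q-model terms raise an error naming the terms;
  pattern-collinear treatment columns in the stacked working models are
  dropped with a warning (e.g. monotone regimen spaces where a past
  treatment is constant).
* m-out-of-n bootstrap: resamples of size $m$ with replacement; percentile
  deviations from the full-sample estimate are rescaled by $\sqrt{m/n}$.
  Coverage is not asserted anywhere: undercoverage is expected in
  post-selection settings, and the tests only check the closed-form
  Gaussian width behavior and reproducibility.

## Known limitations

The stabilizing numerator defaults to a per-time logistic model of $A_t$ on
$L_{01}$, matching the MSM conditioning set. When the true marginalized
treatment probability given $L_{01}$ is not logistic — which is the typical
case once other covariates are integrated out — that numerator model is
mildly misspecified and can contribute a small finite-sample bias to the
stabilized estimator (about $0.02$ on $\mu_2$ at $n = 1000$ under the
benchmark process). `numerator = "marginal"` (per-time frequencies) avoids
this at the cost of less stabilization, and `"none"` gives unstabilized
weights; the unbiasedness checks in the test suite use the marginal form
for exactly this reason.

Propensity models are linear-logistic in the supplied columns; nonlinear
covariate effects or interactions must be supplied as constructed columns.
Post-selection inference is not uniformly valid for any frequentist
selection procedure of this kind — the sandwich standard errors ignore the
selection step, and the m-out-of-n bootstrap is a hook, not a guarantee.
Machine-learning q-estimators and cross-fitting are out of scope; the
working models are parametric by design, and deliberately misspecified
variants are provided to study the consequences. Restricted regimen
spaces are supported through explicit pattern matrices, but dynamic and
stochastic regimes are not.
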