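---
title: "Separable effects for longitudinal mediation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separable effects for longitudinal mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepmed)
```

## The estimands

`sepmed` analyses mediation for a binary baseline exposure $X$, a mediator
$M_t$ and an outcome $Y_t$ measured at waves $t = 1, \dots, T$ (with $M_t$
measured just before $Y_t$). Instead of natural (in)direct effects — which
rest on nested counterfactuals and an untestable cross-world independence
assumption that longitudinal feedback between $M$ and $Y$ routinely violates
— the package targets **separable effects**. The exposure is decomposed into
two components, $X^M$ affecting only the mediator process and $X^Y$
affecting only the outcome process; in observed data $X \equiv X^M \equiv
X^Y$, but the components are conceptually separately manipulable. The
per-wave estimands on the difference scale are

$$
SDE_t = E[Y_t(X^Y\!=\!x, X^M\!=\!x')] - E[Y_t(X^Y\!=\!x', X^M\!=\!x')],
\qquad
SIE_t = E[Y_t(X^Y\!=\!x, X^M\!=\!x)] - E[Y_t(X^Y\!=\!x, X^M\!=\!x')],
$$

which telescope to the total effect $E[Y_t(x)] - E[Y_t(x')]$ (Property P1:
setting both components to $x$ is the same as setting $X = x$). Under
randomised treatment (A0) and the two conditional-independence assumptions —
$M_t \perp X^Y$ given the observed past and $X^M$ (A1), and $Y_t \perp X^M$
given the observed past and $X^Y$ (A2) — the interventional means are
identified by the mediational g-formula: mediator laws are evaluated under
$x'$, outcome laws under $x$, integrating over the simulated histories.

## The two data-generating mechanisms

Two longitudinal mechanisms are implemented end to end (generator, truth
oracle, estimator, study harness).

**Cross-lagged mixed-effect mechanism** (`mixed_spec()`): linear models with
subject-level random effects,

$$
E[M_{it} \mid \cdot] = (\beta_0 + b_{0i}) + \beta_X X_i
  + \beta_{\ell_1(M)} M_{it-1} + \beta_{\ell_1(Y)} Y_{it-1},
$$
$$
E[Y_{it} \mid \cdot] = (\gamma_0 + g_{0i}) + \gamma_X X_i
  + (\gamma_M + g_{Mi}) M_{it} + (\gamma_{\ell_1(M)} + g_{\ell_1(M)i}) M_{it-1}
  + \gamma_{\ell_1(Y)} Y_{it-1},
$$

with $(b_{0i}, g_{0i}, g_{Mi}, g_{\ell_1(M)i}) \sim MVN(0, \Phi)$ and
Gaussian residuals. Wave-1 equations contain no lagged terms — lags are
dropped structurally, not imputed at zero, in the generator. The
identifiability of the separable effects is read off the zero pattern of
$\Phi$ by `check_identifiability()`: diagonal $\Phi$ gives non-parametric
identification; covariance confined within the outcome block
$\{g_0, g_M, g_{\ell_1(M)}\}$ keeps the mediator and outcome processes in
separate (non-recanting) latent districts and identification survives, but
only through the Normality of the random effects; any mediator–outcome
covariance (e.g. $b_0$ with $g_0$) merges the two districts into a single
recanting district and the effects are not identified at all.

**Parallel-process latent growth mechanism** (`lgm_spec()`): repeated
measures load on latent intercepts and slopes, $M_{it} = \eta_{0Mi} +
\lambda_t \eta_{1Mi} + \varepsilon_{Mit}$ (and likewise for $Y$), with
structural equations $\eta_{0M} = \beta_{00} + \beta_{01}X + \zeta_1$,
$\eta_{1M} = \beta_{10} + \beta_{11}X + \zeta_2$, $\eta_{0Y} = \gamma_{00} +
\gamma_{01}X + \zeta_3$ and $\eta_{1Y} = \gamma_{10} + \gamma_{11}X +
\gamma_{12}\eta_{0M} + \gamma_{13}\eta_{1M} + \zeta_4$. The default time
coding $\lambda_t = t - 1$ makes the intercept the wave-1 level and the
slope the per-lag rate of change; alternative codings must be supplied
explicitly and must be strictly increasing. A latent growth model is never
non-parametrically identified — the effects always rest on the Normal latent
structure — but under the latent analogues of A1–A2 they have exact closed
forms, implemented in `lgm_effects()`:

$$
SDE_t = (\gamma_{01} + \gamma_{11}\lambda_t)(x - x'), \qquad
SIE_t = \lambda_t(\beta_{01}\gamma_{12} + \beta_{11}\gamma_{13})(x - x').
$$

## Truth oracles

For the mixed mechanism the package carries two oracles that check each
other. `mixed_effects_closed()` implements the waves-1–2 closed forms
obtained by path tracing and integrating over the random effects. One
subtlety matters: the indirect path $X^M \to M_1 \to Y_1 \to M_2 \to Y_2$
carries the concurrent-mediator coefficient twice, so the expectation over
the random slope contributes its **second moment**,
$E[(\gamma_M + g_M)^2] = \gamma_M^2 + Var(g_M)$ — simply deleting the random
coefficients would understate the wave-2 indirect effect whenever
$Var(g_M) > 0$ (under the reference design: 0.2582 with the correction
versus 0.2032 without). Similarly, the direct path $X^Y \to Y_1 \to M_2 \to
Y_2$ carries $\beta_{\ell_1(Y)} (\gamma_M + g_M)$, i.e. the lagged-outcome
coefficient of the mediator model, giving $SDE_2 = \gamma_X(1 +
\beta_{\ell_1(Y)}\gamma_M + \gamma_{\ell_1(Y)})$. Covariances confined to
the outcome random-effect block multiply terms that are constant across
interventions at these horizons and cancel from the contrasts.

Beyond two waves the number of open paths grows quickly and products of
correlated random slopes accumulate, so the general oracle is Monte Carlo:
`mixed_effects_asymptotic()` forward-simulates the generating recursion with
the exposure split into its components and averages the outcome
*conditional mean* over draws (a Rao–Blackwellisation that removes the
final-wave noise). The three interventions needed for both effects share one
set of random-effect and noise draws, so contrasts are paired and their
Monte-Carlo standard errors small; `draws` below 1000 is refused. Unit tests
use $2\times 10^4$ draws; headline evaluations use $10^6$.

## The estimator

`estimate_effects()` is a three-step parametric mediational g-formula:

1. **Fit** a backend on the panel. `glm`: per-wave (or pooled-across-waves,
   the default) generalised linear models for
   $f_M(M_t \mid X, \bar M_{t-1}, \bar Y_{t-1})$ and
   $f_Y(Y_t \mid X, \bar M_t, \bar Y_{t-1})$, for Gaussian-identity,
   binomial-logit and Gamma-log families. `mixed`: the cross-lagged
   mixed-effect models by maximum likelihood (`lme4`); because the mediator
   likelihood involves only $(b_0)$ and the outcome likelihood only the $g$
   block, the two separate fits are exactly the joint ML whenever the
   cross-block covariance is zero — which is also the only regime in which
   the effects are identified. `lgm`: Gaussian ML on the model-implied
   moments (below).
2. **Simulate** $S$ subjects forward through the fitted laws with the
   exposure components split; mediators and intermediate outcomes are
   sampled, the wave-$t$ mean averages the outcome conditional expectation.
   For the mixed backend, random effects are drawn per simulated subject
   from the estimated $\hat\Phi$; for the latent growth backend the latent
   factors are drawn with mediator-side latents under $x_M$ and
   outcome-side latents under $x_Y$. The three interventions
   $(x', x'), (x, x'), (x, x)$ share random numbers, so
   $\widehat{SDE} + \widehat{SIE}$ equals the total-effect contrast by
   construction. The default $S = 10{,}000$ follows the algorithm's
   guidance; smaller values warn rather than fail so that quick checks stay
   cheap.
3. **Bootstrap**: percentile confidence intervals from $B$ subject-level
   (cluster) resamples, refitting the backend on each resample. Percentile
   intervals and subject-level resampling were chosen because the resampling
   unit must preserve within-subject dependence; normal-approximation
   intervals are not offered.

For the linear-Gaussian latent growth backend the g-formula integral has an
exact closed form in the fitted coefficients (`effect_method = "analytic"`,
equivalent to `lgm_effects()` on the fitted structure); the latent-draw
Monte-Carlo path (`"montecarlo"`) is retained and tested to agree. The
analytic path makes bootstrap loops dramatically cheaper and removes a
Monte-Carlo noise source.

A caution discovered while validating the backends and worth stating
plainly: when the data carry random *slopes* (as the reference mixed design
does), the observed-data conditionals $E[Y_t \mid X, \bar M_t, \bar
Y_{t-1}]$ are **nonlinear** in the history — the random slopes multiply
endogenous regressors — so no linear GLM sequence is correctly specified at
waves beyond the first, however many lags it conditions on. The `glm`
backend is the right tool when subject-level heterogeneity is absent or
enters only through intercepts; under random slopes the `mixed` backend is
the correctly specified estimator.

## The simulation-study harness

`run_scenario()` reproduces one cell of a misspecification or
assumption-violation experiment: simulate $K$ panels, fit a (possibly
deliberately wrong) model, estimate the effects, and summarise per wave the
mean estimate, relative bias $\sum_k(\hat\theta_k - \theta)/(K\theta)$, RMSE
$\sqrt{\sum_k(\hat\theta_k - \theta)^2/K}$, and bootstrap-CI coverage
(`summarize_metrics()`). Replicate seeds derive deterministically from the
master seed, so runs are reproducible and replicates independent. The
misspecification map:

* *mixed, moderate*: the mediator model omits the lagged outcome
  ($\beta_{\ell_1(Y)} \equiv 0$).
* *lgm, moderate*: the outcome latent-slope equation omits the mediator
  latent intercept ($\gamma_{12} \equiv 0$); see below for the disturbance
  structure.
* *severe*: the other mechanism's model class is fitted wholesale — a
  latent growth model to mixed-mechanism data (effects from the fitted
  closed forms) and the mixed model to latent-growth data (effects via the
  g-formula).

## Design choices that were genuinely open

**Disturbance covariance under the moderate latent growth
misspecification.** Dropping the $\eta_{0M} \to \eta_{1Y}$ path while
keeping all four latent disturbances independent forces the ML fit to
distort $\gamma_{13}$ upward (to about 0.256 under the reference design) to
absorb the orphaned mediator–outcome covariance. We instead model the
analyst who removes the causal path but still lets the two latents covary,
reading the association as residual correlation: `fit_lgm(omit_eta0m =
TRUE)` frees the covariance $\psi_{14}$ between the $\eta_{0M}$ and
$\eta_{1Y}$ disturbances (its default; both switches are exposed). With
$\psi_{14}$ free the misspecified model reproduces the true joint
distribution exactly while misattributing the pathway, and the probability
limits are clean omitted-variable expressions:
$\gamma_{11}^* = \gamma_{11} + \gamma_{12}\beta_{01} = 0.3404$ and
$\gamma_{13}^* = \gamma_{13} = 0.19$ under the reference design, so the
wave-2 effects converge to $0.4804$ (SDE, overestimated) and $0.0893$ (SIE,
underestimated — the $\beta_{01}\gamma_{12}$ term is lost). This is the
structure whose consequences the acceptance tests check. Note $\psi_{14}$
cannot be freed together with $\gamma_{12}$: the pair is not jointly
identified.

**Confounder scenarios.** The assumption-violation scenarios add a
subject-level $U \sim N(0, u_{sd})$: in the mixed mechanism to the wave-1
mediator and outcome predictors only (violating A1), in the latent growth
mechanism to $\eta_{0M}$ and to every outcome measurement (violating the
latent A2). The magnitudes are design choices of this package
(`u_effect = 1`, `u_sd = 1` by default). The *direction* of the induced
bias depends on the sign pattern: a shared positive shock on $M_1$ and
$Y_1$ **inflates** the fitted concurrent-mediator coefficient and with it
the indirect effect, while a masking confounder (opposite signs,
`u_effect = c(1.5, -1.5)` in the packaged directional scenario) attenuates
the SIE — increasingly so over waves as the distorted coefficient
compounds. `u_effect` therefore accepts one coefficient per path. Because
the confounder scale is not dictated by the mechanisms themselves, the
violation scenarios are evaluated directionally (attenuation; variance
inflation with near-unbiased points for the latent growth confounder), not
against exact magnitudes.

**Latent growth fitting without an SEM engine.** `fit_lgm()` maximises the
Gaussian likelihood of the stacked $(M_1..M_T, Y_1..Y_T)$ on the
model-implied mean and covariance per exposure arm, with fixed loadings.
Starting values come from two-stage factor-score regressions (per-subject
OLS of each trajectory on $(1, \lambda)$, then structural OLS on the
scores), which are consistent up to measurement attenuation and nearly
exact in practice; BFGS refines them (relative tolerance $10^{-12}$, up to
5 jittered restarts, scale parameters log-transformed). Implementing the
likelihood directly keeps the misspecification switches one-line structural
constraints and makes ~15,000 fits in the bootstrap/coverage experiments
affordable. With exactly noiseless measurements the sample covariance is
singular; the fitter detects this and returns the two-stage solution, which
is exact there. Optional standard errors come from the numerical Hessian.

**Pooled versus stratified sequence fits.** The cross-lagged equations
index coefficients by lag, not by wave, so the pooled fit (one coefficient
set, wave-1 rows entering with structurally-zero lags) is the default
reading; per-wave stratified fits with up to full-history conditioning are
available (`pool = FALSE`, `lag_order`) for g-formula applications that
want wave-specific laws.

**Exposure randomisation** is fixed at $P(X = 1) = 0.5$ (the design says
only that treatment is randomised); residual/measurement standard
deviations default to 1.0 in both generators, a value the reference designs
leave unstated; both are configurable.

## What the generators do and do not emulate

The synthetic panels are balanced, complete, Gaussian, with a binary
exposure constant within subject and first-order lag dynamics. They emulate
the dependence structures that make longitudinal mediation hard —
mediator–outcome feedback, subject-level heterogeneity in mediator effects,
latent trajectory processes, unobserved confounding. They do **not** emulate
dropout or unbalanced designs, time-varying exposures, non-Gaussian
mediators/outcomes in the default designs (the binomial and Gamma families
are supported by the estimator and exercised in tests, but the reference
simulation designs are Gaussian), measurement error in the exposure, or
post-treatment baseline covariates. Passing tests therefore demonstrate
correctness of the machinery under the stated mechanisms, not robustness of
separable-effects estimation on messy cohort data.

## Numerical choices and problem sizes

Monte-Carlo sizes were chosen so every stochastic check has its error
budget stated next to it: oracle agreement and telescoping tests run at
$2\times10^4$ draws with 3-Monte-Carlo-SE tolerances; the headline wave-2
oracle uses $10^6$ draws; recovery tests use $n = 5000$ with 3 estimated
SEs; the misspecification study uses $K = 100$ replicates of $n = 1000$
(the full-size experiment is one argument away); bootstrap coverage is
measured over $K = 100$ replicates of $n = 500$ with $B = 150$ resamples at
$S = 2000$, against the exact closed-form truth of the no-random-effect
design, with the nominal-95% gate at $[0.90, 0.99]$. Percentile intervals
use type-7 quantiles. All randomness flows from explicit seeds; derived
seeds (replicates, bootstrap draws) come from a deterministic child-seed
map, so parallel and serial execution of study replicates agree.

## Known limitations

* Closed-form mixed-mechanism truths stop at wave 2; later waves use the
  Monte-Carlo oracle (by design — the path expansion is the hard part).
* The `glm` backend is inconsistent for mechanisms with random slopes (see
  above); it is the right backend for the application-style setting
  (GLM families, no latent heterogeneity) and for severe-misspecification
  experiments.
* `fit_mixed()` estimates diagonal or outcome-block random-effect
  covariances only; a cross-block covariance would make the target effects
  unidentified anyway, and `check_identifiability()` says so before any
  estimation is attempted.
* Delta-method variances are not offered; uncertainty is bootstrap-only.
* Balanced panels only; unbalanced designs and censoring are out of scope.
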