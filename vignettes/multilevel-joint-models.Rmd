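---
title: "Multilevel joint models for nested longitudinal and survival outcomes"
author: "mjmcrt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel joint models for nested longitudinal and survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cluster randomized trials deliver an intervention at the group level —
classrooms, clinics, villages — and then follow individuals on two
tracks at once: a repeated continuous outcome (for example a mental
health score measured on a fixed schedule) and a time-to-event outcome
(for example time to first clinical diagnosis). The two tracks are not
independent: the level of the longitudinal outcome drives the hazard,
and individuals within a group are correlated on both tracks because
they share the group environment and the group-level treatment
assignment.

A standard joint model (JM) of longitudinal and survival data captures
the first dependence but ignores the second. This package implements a
multilevel joint model (MJM) that captures both, together with a
complete simulation framework for nested trial data and a study runner
that quantifies what is lost when the group level is ignored.

## The model

**Longitudinal submodel.** A three-level linear mixed model: repeated
measurements (level 1) nested in subjects (level 2) nested in groups
(level 3). For subject $j$ in group $l$ at time $t$,

$$y_{jl}(t) = m_{jl}(t) + \varepsilon_{jl}(t), \qquad
m_{jl}(t) = X_{jl}^T\beta + Z_{jl}^T u_{jl} + v_l,$$

with $u_{jl} \sim N(0, \Sigma_u)$ (random intercept and slope by
default), a scalar group-level random intercept
$v_l \sim N(0, \sigma_v^2)$, and
$\varepsilon_{jl}(t) \sim N(0, \sigma_\varepsilon^2)$. The default
fixed-effect design is `1 + time + treatment + time:treatment`; the
treatment-by-time interaction is the treatment effect on the
trajectory. Quadratic trajectories (shared curvature, or curvature by
arm) are available through `mjm_spec(trajectory = ...)`.

**Survival submodel.** A proportional-hazards model with a
piecewise-constant baseline hazard over intervals
$[\tau_{q-1}, \tau_q)$, a group-level frailty $g_l \sim N(0,
\sigma_g^2)$, and a *current-value* association: the log-hazard at $t$
contains $\alpha\, m_{jl}(t)$, the model-implied (noise-free)
longitudinal mean. Rather than integrating the survival function
numerically, the likelihood is carried by an *auxiliary mixed-effects
Poisson model*: each subject's follow-up is split into interval-level
pseudo-observations $\delta_{jlq}$ (event indicator per interval) with
exposure offset $t_{jlq}$, and

$$\log \mu_{jlq} = \log t_{jlq} + \log \lambda_q +
\omega_{jl}^T\gamma + \alpha\, m_{jlq}(t) + g_l .$$

The Poisson likelihood on the pseudo-records is proportional to the
piecewise-exponential survival likelihood — the two differ by
$\sum_{d=1} \log t_{jlq}$, a constant free of parameters — so
posteriors over shared parameters coincide. `log_lik_piecewise_exp()`
and `log_density_survival()` expose both routes, and the test suite
asserts the identity exactly.

**Priors** (see `mjm_priors()`): $N(0, 1000)$ on all regression
coefficients and $\alpha$ (precision 0.001), Inverse-Gamma(0.01, 0.01)
on the residual *variance*, Gamma(0.01, 0.01) on each $\lambda_q$,
Inverse-Wishart(I, $p$) on $\Sigma_u$, and the exact scalar reduction
Inverse-Gamma(1/2, 1/2) of Inverse-Wishart(I, 1) on $\sigma_v^2$ and
$\sigma_g^2$. Two conventions were genuinely open and are resolved as
follows: normal priors written with precision 0.001 are variance 1000
(the convention of BUGS-family samplers), and the Inverse-Gamma prior
acts on $\sigma_\varepsilon^2$, not $\sigma_\varepsilon$ — equivalent
to a Gamma(0.01, 0.01) prior on the precision, again the BUGS-family
convention.

## Estimation

`fit_mjm()` samples the full posterior with JAGS (Gibbs sampling)
through `rjags`. This choice follows the model's natural conjugacy
structure — the longitudinal block is conditionally conjugate and the
Poisson block is handled by slice sampling — and the contract is the
posterior itself, not the kernel: the test suite verifies the sampler
against closed-form posteriors in two conjugate sub-models
(normal–normal for $\beta$ with known residual SD and clamped random
effects; Poisson–gamma for $\lambda_q$ under a null association).

Workflow choices, all configurable via `mcmc_config()`:

* three chains with jittered warm starts (longitudinal least squares
  for $\beta$ and $\sigma_\varepsilon$, interval event rates for
  $\lambda_q$, $\alpha = 0$, random effects at 0) to expose
  initialization sensitivity;
* burn-in and thinning with the split-chain Gelman–Rubin–Brooks
  diagnostic (`rhat()`) and the autocorrelation function
  (`acf_draws()`); a fit's report carries a convergence verdict,
  *converged iff split R-hat < 1.1 on all fixed effects, the
  association, and all variance components* (baseline pieces and
  individual random effects are reported but not gated);
* effective sample sizes by the initial-positive-sequence
  autocorrelation-sum estimator (reported, not gated);
* model comparison by DIC with the *conditional* deviance (conditional
  on random effects, the convention of hierarchical Gibbs samplers),
  $\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with
  posterior means of everything entering $D$ plugged into
  $\bar\theta$. DIC variants differ; this one is stated explicitly
  because it is the one used for trajectory selection among nested
  joint models.

Chain-level RNG streams derive from a single seed, so fits are
bit-reproducible given (seed, configuration, platform).

**Within-interval evaluation of the current value.** The
piecewise-constant construction needs a time point at which
$m_{jlq}(t)$ is evaluated for each pseudo-record; with intervals chosen
to mirror the measurement schedule, the natural choice is the interval
start, which coincides with a measurement occasion. This is the
default (`eval_rule = "interval_start"`), with `"interval_mid"` and
`"event_or_end"` selectable because the convention is genuinely
ambiguous. The choice matters at coarse grids: with three 3-year
intervals the current value lags the trajectory by up to an interval
width, which attenuates the control-arm time slope — visible in the
desk-scale runs below, and consistent with the known degradation of
coarse-interval piecewise hazards.

**Boundary convention.** An observed time exactly equal to an interval
cut belongs to the interval *ending* there, so no zero-exposure record
(undefined log-offset) is ever created; this affects only
measure-zero inputs. The final cut closes the grid at the
administrative end of follow-up, giving every record finite exposure.

## The synthetic-data generator

`generate_dataset()` draws one nested trial: treatment assigned to half
the groups; group effects $v_l, g_l$ and subject effects
$(u_{0jl}, u_{1jl})$; event times by inverting the cumulative hazard
$\Lambda(t) = \int_0^t \lambda_0(s) e^{\alpha m_{jl}(s) + g_l}\,ds$
with Weibull baseline $\lambda_0(t) = \text{scale}\cdot\text{shape}\cdot
t^{\text{shape}-1}$ (adaptive quadrature to 1e-10, Brent root finding
to 1e-8 years); administrative censoring at 9 years; and measurements
every 6 months from 0 to 5 years, kept strictly before the true event
time (a measurement exactly at the event time is excluded). The hazard
depends on the latent $m_{jl}(t)$, not on the noisy $y$, so event times
are invariant to measurement noise — asserted in the tests by swapping
the residual variance without touching the event stream.

Generator defaults are the design conditions used throughout:
$\beta_{000} = 16$, $\beta_{001} = 1.6$, $\beta_{100} = -0.8$,
$\beta_{101} = -2$, $\sigma_{u0}^2 = \sigma_{u1}^2 = 10$, $\rho = 0$,
$\sigma_\varepsilon^2 = 33$, $\alpha = -0.2$; group-level variances
$\sigma_v^2 \in \{5, 18\}$ (group-level ICCs
$\sigma_v^2/(\sigma_{u0}^2 + \sigma_\varepsilon^2 + \sigma_v^2)$ of
0.1 and 0.3) and $\sigma_g^2 \in \{0.4, 1\}$; censoring targets 20%
and 60%; 50/100/200 groups of 30; 11/7/3 hazard intervals — the fully
crossed 72-cell design of `scenario_grid()`. The Weibull *shape* is
not pinned by the design; the default 1.5 (increasing hazard,
qualitatively matching a juvenile-onset diagnosis process) is
configuration, echoed in every output. The *scale* is calibrated to
the censoring target by `calibrate_scale()`: because the scale
multiplies the whole hazard, a subject with scale-free cumulative
hazard $K_i$ at the follow-up end is censored iff
$\text{scale}\cdot K_i < E_i$, $E_i \sim \text{Exp}(1)$, so the
calibrated scale is exactly the $(1-\text{target})$ quantile of
$E_i/K_i$ on a 100,000-subject Monte-Carlo draw — the fixed point that
common-random-number bisection would reach, without iteration.

One master seed per scenario spawns independent substreams per
replicate and per purpose (random effects, event-time uniforms,
measurement noise), so any replicate is reproducible in isolation.

What the generator does *not* emulate: dropout or migration
(censoring is purely administrative), missing measurements before the
event, non-normal outcomes, time-varying group memberships, and
informative censoring. Passing tests therefore demonstrate correctness
of the machinery under the stated generative model, not robustness to
these real-data features.

## The cost of ignoring the group level

`compare_models()` fits the three-level MJM and the two-level JM
(`mjm_spec(multilevel = FALSE)`, which removes $v_l$ and $g_l$ and is
*exactly* nested: with $v \equiv g \equiv 0$ the two log-posteriors
coincide, as the tests assert) on byte-identical replicate datasets and
tabulates mean estimates, bias, relative bias, MESE (mean over
replicates of the posterior SD) and ESE (SD over replicates of the
posterior means). Non-converged replicates are excluded and counted.
The headline contrasts are the treatment-by-time interaction, the
control-arm time slope, and the association.

## Problem sizes and numerical choices

The package's own checks run at desk scale, chosen once as the
smallest sizes at which the phenomena of interest are identifiable:

* calibration checks: 100,000 Monte-Carlo subjects, achieved censoring
  within 0.01 of target;
* the recovery fit: 30 groups of 15 subjects, 20% censoring, 3 hazard
  intervals, 3 chains x 500 kept draws (thin 4, burn-in 2000) — the
  treatment-by-time effect and the association recover within
  posterior uncertainty; the control-arm slope at this coarse grid
  shows the attenuation discussed above, so its check is directional;
* the paired MJM/JM comparison: 24 groups of 12, 7 intervals, 3 paired
  replicates — enough to see the direction and rough magnitude of the
  group-level attenuation, not to estimate it precisely;
* conjugate and thinning checks: 8 groups of 8, 2 intervals.

Numerical conventions: quantiles are type-7 (linear interpolation);
the split R-hat returns `Inf` when chains are separated with zero
within-chain variance and `NaN` for fully degenerate input; a constant
chain's autocorrelation is `NaN` with a warning; `log_prior()` returns
$-\infty$ outside the support instead of erroring; exposures are
strictly positive by construction. `log_posterior()` is over the
original (constrained) parameters and `log_posterior_grad()` is its
exact analytic gradient (variance components on the variance scale,
$\Sigma_u$ by lower triangle), verified against central finite
differences.

## Known limitations

* Only the current-value association is implemented; shared-random-
  effects, current-slope and cumulative linkages are out of scope.
* Survival covariates are time-fixed (plus the current-value term).
* No left truncation, interval censoring, competing risks, or
  recurrent events.
* Group-level variance estimates shrink toward zero in small designs —
  an expected behavior of hierarchical Bayes at modest group counts,
  most visible in the frailty SD.
* A single longitudinal outcome; no multivariate extension.
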