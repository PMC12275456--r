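---
title: "Simulation-based power analysis for semi-field vector-control experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for semi-field vector-control experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfepower)
```

## The design problem

Semi-field systems (SFS) are enclosed, partitioned habitats in which candidate
malaria vector-control tools — insecticide-treated nets (ITN), pyriproxyfen
autodissemination (PPFa), sugar baits, repellents — are trialled on real
mosquito populations before committing to field trials. The replication unit
is the *chamber*: a compartment of the enclosure into which mosquitoes are
released or emerge and from which they are recaptured. Chambers are scarce
(typically 2–16 per system), counts are small, and abundance varies between
chambers for reasons unrelated to the intervention (host attractiveness,
microclimate, recapture technique). Classical closed-form power calculations
do not cover count outcomes with multiple levels of random variation, so the
realistic route is simulation: generate data from the same generalized linear
mixed model (GLMM) that will be used for the analysis, refit it many times,
and count how often the intervention effect is detected.

`sfepower` implements that loop end to end: design specification, simulation,
maximum-likelihood GLMM fitting, and Monte-Carlo power and type-I error
estimation over grids of design choices.

## Generative models

**Short-term experiments** (24–48 h, a single recapture occasion) use a
Poisson GLMM with a chamber random intercept. With `itn` and `ppf` as 0/1
indicators, chamber $j$ has

$$y_j \sim \mathrm{Pois}(\lambda_j), \qquad
\log \lambda_j = \beta_0 + \beta_I\,\mathrm{ITN}_j + \beta_P\,\mathrm{PPF}_j
+ \beta_{I,P}\,\mathrm{ITN}_j\mathrm{PPF}_j + c_j, \qquad
c_j \sim N(0, \sigma_c^2).$$

Single-intervention designs drop the PPFa terms. A Poisson conditional is
used because with one observation per chamber there is no information to
separate observation-level overdispersion from the chamber variance.

**Long-term experiments** (12 weeks, repeated sampling) use a
negative-binomial GLMM with *crossed* random intercepts for chamber and
sampling occasion:

$$y_{i,j} \sim \mathrm{NB}(\lambda_{i,j}, \theta), \qquad
\log \lambda_{i,j} = \beta_0 + \beta_T t + \beta_I\,\mathrm{ITN}
+ \beta_{T,I}\, t\,\mathrm{ITN} + \dots + \tau_i + c_j,$$

with $\tau_i \sim N(0, \sigma_\tau^2)$ shared by every chamber sampled at
occasion $i$, and variance $\lambda + \lambda^2/\theta$. Here interventions
act *dynamically*: their effects are time slopes ($\beta_{T,I}$,
$\beta_{T,P}$, $\beta_{T,I,P}$), and the static terms and the time main
effect are zero in the generative model. They are nevertheless always kept
in the fitted model, because with real data nothing licenses assuming them
away.

### Effect sizes

A target effect is specified as the proportion of the mosquito population
removed by the end of the experiment; its complement exponentiates to the
model coefficient, e.g. an 80% reduction gives $\beta = \log(0.2)$.
Combined interventions without interaction multiply their remainders
(80% ITN × 70% PPFa leaves $0.2 \times 0.3 = 6\%$), and an interaction
removes an extra fraction of that remainder (a 50% interaction halves 6% to
3%). For long-term designs the same reductions are reached at the *end* of
the experiment: time is normalised to $(0, 1]$ over the 12 weeks, so the
slope coefficient equals $\log(1-r)$ evaluated at $t = 1$. This
normalisation is a design choice of the package; it makes effect-size
semantics identical across horizons. Sampling frequencies map to equally
spaced normalised times ($K = 3$ monthly, 6 fortnightly, 12 weekly, 90
daily) with no baseline sample at $t = 0$; the first observation is made at
the first sampling point.

```{r effects}
reduction_to_log_effect(0.8)
combined_remaining(0.8, 0.7)
apply_interaction(combined_remaining(0.8, 0.7), 0.5)
```

## Default parameters

| quantity | default | meaning |
|---|---|---|
| `chamber_var` ($\sigma_c^2$) | 0.1807 | log-scale inter-chamber variance, estimated from published mesocosm data; sensitivity sweeps scale it by 0.5×, 1×, 2×, 5× |
| `time_var` ($\sigma_\tau^2$) | 0.2266 | log-scale between-occasion variance, same source |
| `theta` ($\theta$) | 10 | NB dispersion; $10^6$ is treated as the Poisson limit |
| `lambda` | — | expected mosquitoes recaptured per control chamber (per occasion for long-term); $\beta_0 = \log\lambda$ |
| `alpha` | 0.05 | two-sided Wald significance threshold |
| sufficient power | 0.80 | reporting flag only |

The canonical study grids are 2/4/6/8 chambers per treatment;
5–100 recaptured mosquitoes (short-term) or 1–40 sampled per occasion
(long-term); reductions of 0/40/50/60/80%.

## Fitting

The fitters are the package's own maximum-likelihood implementations; they
are cross-checked in the test suite against independent implementations
(`lme4`, `glmmTMB`) and against brute-force integration oracles.

* **Poisson, one random intercept** — the chamber intercept is integrated
  out by *adaptive* Gauss–Hermite quadrature (default 15 nodes; all
  observations of a chamber share one intercept, so the conditional mode and
  curvature have closed Newton updates and the quadrature is recentred per
  chamber). Doubling the node count changes estimates by well under $10^{-4}$.
* **Negative binomial, crossed intercepts** — the joint mode over
  $(\tau, c)$ is found by damped Newton on the joint log-density, whose
  negative Hessian has a 2×2 block structure (diagonal blocks plus the
  occasion-by-chamber weight matrix) that is dense-Cholesky factorised
  directly; the marginal likelihood is the Laplace approximation at that
  mode, maximised jointly over fixed effects, both log standard deviations
  and $\log\theta$.
* **Boundary policy** — standard deviations are optimised on the log scale;
  whenever an estimate collapses towards zero the profile with that
  component removed (for the short-term model, an ordinary Poisson GLM) is
  also fitted and the better likelihood wins, so singular fits are reported
  as exactly zero variance with `boundary = TRUE`. A dispersion estimate at
  the $10^6$ cap is flagged as the Poisson limit. This mirrors the boundary
  behaviour of standard mixed-model software, which is precisely what drives
  small-sample type-I inflation.
* **Standard errors and tests** — fixed-effect covariance is the inverse
  observed information of the (approximate) marginal log-likelihood at the
  optimum, with variance parameters held at their estimates — the usual GLMM
  Wald convention. Each coefficient gets a two-sided Wald $z$ test;
  p-values are deliberately *uncorrected* (no parametric bootstrap), because
  the behaviour of plain Wald tests is itself part of what the framework
  measures, and bootstrap corrections are far too slow inside a
  simulation-based power loop.
* **Robustness** — up to three jittered optimiser restarts precede a
  `converged = FALSE` verdict; degenerate data (an all-zero arm) yield a
  flagged fit with a huge standard error, never an exception.

## Power estimation

`estimate_power()` simulates `n_sim` datasets, refits the generating model,
and reports the proportion of Wald p-values below `alpha` among converged
fits, with a Wilson score 95% interval (chosen for its sane behaviour at
0/1; the interval method is a package choice). 1000 simulations give a
margin of error of ±2.5 points at 80% power. Non-converged fits are
excluded from the denominator by default and their rate reported; counting
them as non-significant is available via `nonconverged = "nonsignificant"`.
When the tested term's generating effect is zero the same machinery
estimates the type-I error rate (`estimate_type1()`), which should be
compared with the nominal 5% before trusting power numbers: with 2–4
chambers per treatment the Wald test is markedly anticonservative.

Reproducibility follows a substream contract: each simulated dataset's seed
is derived from (master seed, scenario index, replicate index), so grid
cells can be recomputed in isolation, interrupted `run_grid()` sweeps resume
from their checkpoint bit-identically, and results do not depend on
execution order.

## What the simulator does and does not emulate

The generator reproduces the stochastic skeleton of a semi-field trial:
Poisson/NB counts, log-normal chamber heterogeneity, shared occasion shocks,
factorial arm structure. It does not model mosquito population dynamics
(removals feed back on abundance under daily sampling in reality), Latin
square rotation of chambers, released-vs-recaptured binomial structure
(recommended when recapture rates exceed ~80%), or covariates such as host
or volunteer identity. Passing tests therefore certify the statistical
machinery under the stated model, not the fidelity of that model to any
particular semi-field system.

## Numerical choices and test problem sizes

Quadrature uses 15 adaptive Gauss–Hermite nodes (1 node = Laplace);
inner Newton iterations stop at step $10^{-9}$ (crossed model) or
$10^{-12}$ (scalar modes); variance standard deviations are bounded in
$[10^{-4}, 10]$ on the native scale and $\theta$ in $[10^{-3}, 10^6]$.
The test suite sizes its Monte-Carlo checks to run on a desk machine:
likelihood-oracle comparisons on 4–8-chamber instances (dense-grid
integration to $10^{-4}$; plain Monte-Carlo integration of the crossed
model on a 2-occasion × 4-chamber fixture), parameter recovery at 80–300
replicates with tolerances tied to the empirical Monte-Carlo standard
error, and power scenarios at 120–250 replicates judged at binomial
tolerance; the acceptance script runs the headline short-term scenarios at
the full 1000 replications and the long-term type-I scenario at 500.

## Known limitations

* Wald $z$ tests in small samples are the object of study, and they behave
  accordingly: boundary (zero-variance) fits shrink standard errors and
  inflate the false-positive rate well above 5% at 2–4 chambers per
  treatment, and near-separated arms (expected counts below ~1 per chamber,
  as in strong combined-intervention arms) push the Wald statistic towards
  zero even when the evidence is overwhelming (the Hauck–Donner effect), so
  Wald-based power can understate the evidence an LRT would find. Both
  phenomena are faithfully reproduced, not corrected.
* The Laplace approximation for the crossed NB model is least accurate at
  very small counts (`lambda` ≈ 1) with few occasions; the test suite bounds
  its error against Monte-Carlo integration on small instances only.
* Power estimates inherit binomial Monte-Carlo noise; compare designs with
  paired seeds (the default substream contract does this) rather than across
  independent runs.
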