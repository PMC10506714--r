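---
title: "A hierarchical Bayesian decomposition model for daily stream water temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Bayesian decomposition model for daily stream water temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Stream ecologists need complete daily water-temperature (WT) series to study
thermal effects on freshwater organisms and to project them under climate
warming, but monitored WT records are typically short and gappy, while air
temperature (AT) -- and often river discharge (Q) -- are long and nearly
complete. `streamtemp` fits a hierarchical Bayesian model that transfers
information from the covariates to WT at two distinct frequencies, then uses
the joint posterior to impute gaps, hindcast, forecast, and translate AT
warming scenarios into WT warming distributions.

## The model

Every daily series $X_t$ (WT, AT, and log-discharge) is decomposed into a
six-month-window mean, an annual sinusoid and a short-term residual:

$$X_{y,t} = \alpha_y + \beta_y \sin\!\Big(\frac{2\pi}{n}(t - t_0)\Big) + \epsilon_t,$$

where $y$ indexes calendar half-year windows (January--June, July--December),
$t$ is day of year, $n$ is the number of days in that calendar year (365 or
366) and $t_0$ is a phase in days. Windows are deliberately aligned on
calendar half-years so two datasets always agree on window boundaries;
partial windows at the series edges are estimated like any other window but
flagged, so summaries can exclude them. Each series carries its own phase:
the linkage between series happens through the regressions below, not
through a shared $t_0$.

For the covariates, $\epsilon_t$ is a zero-mean stationary AR1 process with
autocorrelation $\rho$ and innovation scale $\sigma$; the first point follows
the stationary law $N(0, \sigma^2/(1-\rho^2))$.

The WT windows are not free. Reparametrizing each window by its seasonal
extrema, $\max_y = \alpha_y + \beta_y$ and $\min_y = \alpha_y - \beta_y$, the
WT extrema are regressed on those of the covariates:

$$\max_y^{WT} \sim N(\theta_0 + \theta_1 \max_y^{AT} + \theta_2 \min_y^{Q},\ \sigma^2_{max}), \qquad
  \min_y^{WT} \sim N(\theta_0' + \theta_1' \min_y^{AT} + \theta_2' \max_y^{Q},\ \sigma^2_{min}).$$

Pairing the WT maximum with the discharge *minimum* (and vice versa) encodes
the hydrological intuition that summers with low flow run warm and winters
with high flow run mild. Discharge enters on the natural-log scale
throughout, so proportional flow changes act additively. Without a discharge
series the $\theta_2$ terms are identically zero.

Daily WT deviations are handled in two selectable ways:

* **M1** (the simpler reference variant): WT residuals follow their own
  zero-mean AR1 process, exactly like the covariates.
* **M2** (the default): WT residuals are regressed on the *daily* covariate
  residuals,
  $$\epsilon^{WT}_{y,t} = \delta\,\epsilon^{AT}_{y,t}
      + \gamma\,\epsilon^{Q}_{y,t}\,
        \sin\!\Big(\frac{2\pi}{n}(t - t_0 + n/2)\Big) + \zeta_t,$$
  with white noise $\zeta_t \sim N(0, \sigma^2_\zeta)$. The sine factor is in
  strict antiphase with the WT seasonal cycle (the $n/2$ shift): a positive
  flow deviation cools the stream at the seasonal maximum (modifier $-1$) and
  warms it at the minimum (modifier $+1$), with a smooth transition between.

Because the three modules form one joint hierarchical model, every unknown WT
day -- an interior gap, a hindcast year before the WT record, or a forecast
period appended to the covariate series -- is a latent variable of the fit,
and its posterior predictive distribution carries all parameter, window and
residual uncertainty simultaneously.

### Identifiability choices

$\alpha + \beta\sin(\cdot)$ is invariant under $(\beta, t_0) \to (-\beta,
t_0 + n/2)$, so amplitudes are constrained nonnegative and phases to $[0,
365)$. The covariate amplitudes carry an explicit $\beta \ge 0$ prior
truncation. The WT amplitude, being derived from the extrema regression as
$(\max_y - \min_y)/2$, is *not* truncated: the printed regression is a plain
Normal, and under any realistic seasonal contrast (window extrema separated
by many regression standard deviations) the posterior probability of a
negative WT amplitude is negligible. The tests assert that every posterior
draw satisfies it.

The extrema regression is printed with a single intercept in some
formulations; the package defaults to two distinct intercepts
($\theta_0, \theta_0'$) -- the maxima and minima of a river need not share
one -- and `stm_config(shared_intercept = TRUE)` ties them for users who want
the single-intercept form.

## Priors

Priors are weakly informative relative to daily temperature data
(`default_priors()`): $N(0, 10^2)$ on every regression coefficient and on
$\delta, \gamma$; Uniform$(-1, 1)$ on autocorrelations; Uniform$(0, 365)$ on
phases; $N(\text{empirical window mean}, 10^2)$ on covariate window means;
half-Normal$(10)$ on covariate amplitudes; and half-Normal with scale twice
the empirical residual spread (from a least-squares sinusoid fit) on every
scale parameter, so the prior stays flat over the plausible range whatever
the units of the discharge record. All entries can be overridden, and
overrides are validated against the model's invariants before any
computation starts.

## Computation

The joint posterior is written out once, in R, as `joint_logposterior()` --
the reference statement of the model, tested term by term against an
independently coded oracle. Sampling uses a model-tailored
Metropolis-within-Gibbs scheme (compiled, `src/sampler.cpp`). Conditional on
the phases, autocorrelations and scale parameters, *every* remaining
parameter -- window means and amplitudes, WT window extrema, the
$\theta$-block, $\delta$ and $\gamma$, and all latent missing values -- has
an exactly Gaussian full conditional, which the sampler draws exactly:
regression blocks through small conjugate multivariate-normal draws, scalar
sites through a quadratic fit to the local conditional log-density (exact
for a Gaussian conditional, three evaluations, so every scalar update shares
one code path). The remaining scalars use random-walk Metropolis with scales
adapted toward 44% acceptance during burn-in and frozen afterwards. The
phase/scale scalars and the WT extrema are the slowest-mixing sites, so each
sweep repeats that block five times -- cheap relative to the conjugate window
sweeps.

Two structural points matter for correctness:

* Under M2, latent missing WT days are likelihood leaves (nothing else
  depends on them), so parameter conditionals use the observed WT days only
  and the latent days are redrawn each sweep from their exact predictive law
  (a partially collapsed Gibbs scheme). Under M1 the WT AR1 chain couples the
  latent days and they participate in the conditionals.
* Covariate gaps are sampled exactly like WT gaps, through their AR1
  structure plus (under M2) the information flowing back from observed WT
  via $\delta$ and $\gamma$.

Chains start from a least-squares decomposition (common phase from a
sin/cos regression, per-window amplitudes, moment estimates of $\rho$,
$\sigma$) with chain-specific jitter. Fully prior-dispersed phase starts were
rejected deliberately: $t_0$ is circular, and a chain started half a year out
of phase must cross a deep density valley, which no local sampler does in
finite burn-in; the jittered least-squares start preserves overdispersion in
every well-identified direction while keeping all chains in the single
physically meaningful phase mode.

Two MCMC presets are provided. `desk` (3 chains, burn-in 4000, 2000 kept,
no thinning, a few tens of seconds on a 13-year daily dataset) is the
package default and what the simulation experiments below use; burn-in 4000
rather than 2000 is needed for the phase parameters to merge from
overdispersed starts (split $\hat R$ up to 1.18 at 2000, below 1.1 at 4000).
`paper` (3 chains, burn-in 10000, thinning 25, 10000 kept) mirrors the heavy
settings traditionally used for final fits. Each chain's RNG stream derives
from one integer seed and reruns are bit-for-bit reproducible. The
convergence report flags any parameter with split $\hat R > 1.1$ or
effective sample size below 100.

## Evaluation suite

`chi2_discrepancy()` implements the posterior $\chi^2$ check
$\chi^2(WT, \theta) = \sum_{y,t} (WT_{y,t} - E[WT_{y,t}|\theta])^2 /
\mathrm{Var}[WT_{y,t}|\theta]$ over observed days, with replicated data drawn
per posterior draw from the same conditional law; the Bayesian p-value is the
probability that the replicated discrepancy exceeds the observed one (about
0.5 means congruence, about 0.05 or 0.95 is a warning). For M1 the
conditional law is the one-step AR1 predictive; for M2 it is the daily link
law with variance $\sigma_\zeta^2$.

`stm_dic()` computes the deviance over *observed WT days only* (covariate
likelihood terms excluded), so M1 and M2 are compared on identical
observations; this scope is a deliberate choice the function documents, and
the plug-in uses the posterior mean of parameters and latent values (the
classic $p_D = \bar D - D(\bar\theta)$ definition rather than the
half-variance form). A roughly five-point DIC gap is the customary
meaningful-difference yardstick.

`cross_validate()` splits chronologically at $\lfloor 2T/3 \rfloor$ days (the
fraction is configurable), masks the tail WT, refits, and scores the
posterior-mean point prediction (median by flag) by RMSE over observed tail
days. `halfyear_discrepancy()` gives the posterior of replicated-minus-
observed six-month means per window, using observed days in both terms.

`project_warming()` translates a uniform AT offset $\Delta$ into WT warming
through the seasonal pathway only: shifting every AT window extremum by
$\Delta$ moves the annual-mean WT by $((\theta_1 + \theta_1')/2)\,\Delta$ in
each posterior draw (the seasonal maximum by $\theta_1 \Delta$, the minimum
by $\theta_1' \Delta$). A uniform shift leaves the daily AT *deviations*
unchanged, so $\delta$ contributes nothing to mean warming; this
interpretation -- scenario warming acts on the seasonal signal, not the daily
anomalies -- is a documented modelling decision, and warming is therefore
exactly linear in $\Delta$ draw by draw, a property the tests exploit.

## The simulator and what passing tests mean

`simulate_dataset()` runs the model forward with known parameters: covariate
window means and amplitudes drawn around stated values (optional linear trend
on the means), AR1 residuals, WT extrema through the link regression, daily
WT through the M2 link (or M1 AR1), and masking applied last with
geometric-length gaps. The default scenario mimics a temperate Atlantic
river of medium size: 13 years, WT mean 12.9 degC, AT mean 12.4 degC with
seasonal amplitude about 6 degC peaking in late July ($t_0 = 113$),
log-discharge mean 1.6 (about 5 m$^3$/s) in antiphase with temperature,
$\delta = 0.6$, $\gamma = 0.5$, $\sigma_\zeta = 0.5$ degC, and about 27% of
WT days missing in multi-week gaps. Between-window variability of
$\alpha_y, \beta_y$ is independent Gaussian around the scenario means -- the
model itself places no between-window law on them, so the generator uses the
simplest one.

The simulation experiments in the test suite use this generator at reduced
scale (three- and four-year series, 10% WT gaps, 20 replicates, desk preset)
to keep a full run in minutes: parameter recovery with nominal credible-
interval coverage, calibration of the $\chi^2$ p-value near 0.5 under the
generating model, and the forecasting ordering -- cross-validation RMSE of M2
below M1 on link-generated data, with M2 approaching the $\sigma_\zeta$
floor. Passing them shows the inference machinery is correct and calibrated
*under the model's own assumptions*. Real rivers violate those assumptions
in known ways -- residuals are not exactly AR1, the AT link is weaker in
winter under ice or snowmelt, window parameters drift with land use -- so
performance numbers on simulated data bound, but do not guarantee, behaviour
on monitoring data.

## Numerical notes

* The extrema reparametrization is exact algebra; round trips are
  bit-for-bit when the sums are exactly representable and within one IEEE
  rounding (relative $10^{-15}$) otherwise.
* A six-month window mean equals $\alpha_y$ plus the within-window average
  of the sinusoid; for calendar windows with the default phase that average
  is not zero (up to about a quarter of the amplitude), which is why summary
  functions compare window means against the full seasonal signal, not
  against $\alpha_y$ alone.
* Invalid parameter states (nonstationary $\rho$, nonpositive scales,
  negative covariate amplitude, out-of-range phase) make
  `joint_logposterior()` return $-\infty$ rather than raise, so samplers can
  treat them as rejected states.
* Nonpositive discharge values are floored at a configurable
  $\varepsilon = 0.001$ m$^3$/s before the log transform, with a warning.
* The degenerate missingness draw that would mask every observation aborts
  with an error rather than returning an unusable series.

## Limitations

One station, one river: multi-station hierarchies, riparian-shading
covariates and sub-daily resolution are out of scope. Scenario-mode warming
reuses the training-period window structure; it does not attempt
rainfall-runoff modelling of future discharge. The DIC of models with very
different latent structure (M1's flexible AR1 versus M2's link) rewards
in-sample flexibility, so a missing-data-heavy record can rank M1 ahead on
DIC even when M2 forecasts better -- the cross-validation RMSE is the more
decision-relevant metric, and the two are reported side by side.
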