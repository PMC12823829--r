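---
title: "Modelling survival gains from earlier emergency calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling survival gains from earlier emergency calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcasim)
```

## The problem

Survival after out-of-hospital cardiac arrest is extraordinarily
time-sensitive: the literature consistently reports a 5–12% drop in survival
probability for each minute between collapse and treatment. Mean ambulance
response times differ by a factor of three or more between urban and remote
municipalities, so the *same* physiological event carries very different
survival odds depending on where it happens. The question this package
addresses is counterfactual: how much of that gap could be closed if the
emergency call — the first link in the chain of survival — happened a few
minutes earlier?

## The model and its assumptions

Survival at treatment delay $t$ (minutes) is modelled as exponential decay,

$$S(t) = S_0 \, (1 - r)^{\,t - t_0},$$

with per-minute decline rate $r$. The model deliberately carries no
covariates: no bystander-CPR rates, defibrillator access, or case-mix
adjustment. It is a transparency-first approximation whose single parameter
$r$ is *configured*, not estimated — the default $r = 0.07$ is the midpoint
of the published 5–12% range, and `sensitivity_over_r()` sweeps that range
to show how every conclusion moves with it.

Two parameterizations are supported:

* **Absolute** (the default, `s0 = 1`, `t0 = 0`): survival is an absolute
  probability of the full delay, so a municipality with mean response time
  $T$ has baseline survival $(1-r)^T$. This is the reading under which the
  published four-municipality table is reproduced cell for cell, and it is
  what `build_scenario_table()` uses.
* **Relative** (`t0 =` a reference time, `s0 =` survival there): useful when
  survival at some observed delay is known and only *changes* relative to it
  matter. The two coincide when $S_0 = (1-r)^{t_0}$.

An earlier call by $\Delta$ minutes shifts the effective delay to
$\max(T - \Delta, 0)$. Shifts at least as large as the response time are
**capped** at $t = 0$ (survival $S_0$) and flagged, rather than rejected:
a call cannot precede the collapse, and erroring would break parameter
sweeps that cross that line.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `r` | per-minute decline (fraction/min) | 0.07 | midpoint of the reported 5–12% range |
| `s0`, `t0` | reference survival and time | 1, 0 min | absolute parameterization (above) |
| `deltas` | call advances (min) | 1, 5, 10 | the scenario set of the source analysis |
| `n_iter` | Monte Carlo iterations | 10,000 | matches the source analysis; mean SE $\sigma/\sqrt{n} = 2\times10^{-4}$ at the default $\sigma$ |
| `noise_sigma` | noise SD (probability scale) | 0.02 | see below |
| `interval` | percentile band | 2.5, 97.5 | the 95% simulation interval |

The noise scale is the one genuinely open choice: the study design fixes
only the noise *mean* (zero). We default to $\sigma = 0.02$ on the
probability scale — small enough that bands stay interpretable as
"stochastic variability around the curve", large enough to be visible — and
echo it in every output's metadata so no result is ever detached from the
$\sigma$ that produced it. Noise is drawn independently per iteration and
per grid point; a `"time"` mode (perturbing $t$ instead of $S(t)$) is
provided as the alternative reading of noise "around the curve", but is not
the default.

## Numerical conventions

* **Clipping.** Every Monte Carlo draw is clipped to $[0,1]$ *before*
  summarizing. Near the boundaries this biases the mean toward the interior
  by up to $\sigma\phi(z)$ (with $z$ the distance to the boundary in units
  of $\sigma$); away from them — $S(t) \in [3\sigma, 1-3\sigma]$ — the bias
  is negligible and the mean converges to the deterministic value at the
  usual $\sigma/\sqrt{n}$ rate. Tests assert the CLT bound only in that
  interior region, which is the honest domain of the claim.
* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), stated so that a seed reproduces results bit
  for bit.
* **Seeding.** One seed governs a whole run; municipality $i$ simulates
  with `seed + i - 1` so curves are mutually independent yet the run is
  reproducible from a single integer. The generator name is recorded in the
  output metadata, and every simulation restores the caller's RNG state.
* **Rounding.** Rendered percentages round half *away from zero* to one
  decimal (47.65 → 47.7), the convention of the printed tables this package
  mirrors; unrounded fractions are always written alongside (JSON twin) so
  rounding never accumulates.
* **Degenerate inputs.** Empty cohorts yield empty tables (not errors);
  duplicate municipality names, non-positive response times, unsorted time
  grids, negative delays and malformed configurations all fail fast with
  named errors.

## The synthetic-data generator

`generate_cohort()` emulates a municipality registry: categories drawn from
a configurable mix, response times from per-category lognormal
distributions — the simplest strictly positive, right-skewed family. The
default medians (big city 10, mountain 17, rural 23, island 33 min) are
centred on the four observed municipality means, used purely as distribution
centers. `generate_observations()` produces noisy survival readings
$\mathrm{clip}(S(t) + \varepsilon)$, flagging draws that were clipped.

`estimate_decay_rate()` closes the loop: under the model
$\log S(t) = \log S_0 + t\log(1-r)$, so ordinary least squares on
$\log s_{obs} \sim t$ recovers $r$ — exactly from noise-free data, and
within ±0.01 in ≥95% of seeded replicates at $\sigma = 0.01$ with 200
observations over 0–30 min (the suite checks both). Clipped and non-positive
observations are excluded from the fit and counted, because the log
transform is undefined at zero and badly biased near it. Log-domain least
squares was chosen over nonlinear fitting for transparency; its
heteroskedasticity on the probability scale is accepted, documented bias
being the price of a closed-form, assumption-light estimator.

What the generator does *not* emulate: incident-level variation within a
municipality, seasonal and weather effects, call-handling heterogeneity, or
any empirical Norwegian registry microstructure. Passing tests therefore
demonstrate that the pipeline is *self-consistent* — it recovers the
parameters of its own data-generating process — not that the exponential
model is correct for real arrests.

## Worked run

```{r table}
cohort <- example_municipalities()
tab <- build_scenario_table(cohort, decay_params(r = 0.07), deltas = c(1, 5, 10))
format_scenario_table(tab)
compute_gains(tab)
```

```{r mc}
result <- run_analysis(cohort, t_grid = seq(0, 40, 1),
                       mc_cfg = mc_config(n_iter = 10000, noise_sigma = 0.02,
                                          seed = 1))
head(result$summaries$Bergen)
```

```{r plot, eval = requireNamespace("ggplot2", quietly = TRUE), fig.width = 6, fig.height = 4}
plot_mc_curve(result$summaries$Bergen, title = "Bergen")
```

Problem sizes throughout the package's tests are desk-scale by design:
four-municipality tables, 10,000-iteration simulations over a 0–40 min grid,
and recovery studies of 100 replicates × 200 observations — all complete in
seconds on one core.

## Known limitations

* The exponential decay with a single global $r$ is the strongest
  assumption; real decline rates differ by initial rhythm, bystander CPR and
  defibrillation access, none of which are modelled. Conclusions should be
  read as *comparative* (between municipalities and scenarios), not as
  absolute survival predictions.
* Municipality *means* hide the response-time distribution; a mean of 22.6
  min with heavy right skew implies different scenario gains than the same
  mean tightly concentrated. The synthetic module can emulate such skew, but
  the headline table cannot correct for it.
* The Monte Carlo stage propagates a stylized noise, not physiological or
  epidemiological uncertainty; its bands are simulation intervals, not
  confidence intervals.
* Capping at $t = 0$ makes large-$\Delta$ survival exactly $S_0$, an
  optimistic boundary (instant treatment), flagged in the output so users
  can filter such cells.
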