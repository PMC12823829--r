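# ohcasim

Survival after out-of-hospital cardiac arrest (OHCA) falls by roughly 5–12%
for every minute that treatment is delayed. `ohcasim` turns that fact into a
small, transparent analysis pipeline for emergency-medicine researchers and
EMS planners: given municipality-level mean ambulance response times, it
quantifies how much survival would improve if the emergency call were placed
1, 5, 10 — or any Δ — minutes earlier, with Monte Carlo simulation intervals
and a sensitivity sweep over the decline rate.

## The model

Survival as a function of treatment delay `t` (minutes) is modelled as
exponential decay

```
S(t) = S0 · (1 − r)^(t − t0)
```

where `r` is the per-minute decline rate (default 0.07, the midpoint of the
5–12% range reported in the resuscitation literature), and `S0` is survival
at the reference time `t0`. With the default absolute parameterization
(`S0 = 1`, `t0 = 0`), a municipality with mean response time `T` has
baseline survival `(1 − r)^T`, and a call placed Δ minutes earlier shifts
the effective delay to `max(T − Δ, 0)`.

Around the deterministic curve, a Monte Carlo stage adds Gaussian noise
(mean 0, configurable σ, default 0.02 on the probability scale), clips each
draw to [0, 1], and reports the mean and the 95% simulation interval
(2.5th–97.5th percentiles) over 10,000 iterations.

A synthetic-data module generates municipality cohorts (lognormal response
times by geography category) and noisy survival observations, and recovers
`r` by log-linear least squares — so every stage is testable without any
external data.

## Worked example

```r
library(ohcasim)

cohort <- example_municipalities()   # four Norwegian municipalities (AMK data)
tab <- build_scenario_table(cohort, decay_params(r = 0.07), deltas = c(1, 5, 10))
format_scenario_table(tab)
#> # A tibble: 4 × 7
#>   name    category response_min survival_0 survival_d1 survival_d5 survival_d10
#>   <chr>   <chr>           <dbl> <chr>      <chr>       <chr>       <chr>
#> 1 Bergen  big city         10.2 47.7%      51.3%       68.6%       98.6%
#> 2 Tokke   mountain         16.6 30.0%      32.2%       43.1%       61.9%
#> 3 Lurøy   island           32.8 9.3%       9.9%        13.3%       19.1%
#> 4 Sørfold rural            22.6 19.4%      20.9%       27.9%       40.1%
```

Each row is one municipality; `survival_0` is baseline survival at its mean
ambulance response time, and `survival_d<Δ>` the survival if the call came Δ
minutes earlier. Bergen (10.2 min response) starts at 47.7% and approaches
near-universal survival with a 10-minute head start; the island municipality
Lurøy (32.8 min) roughly doubles its survival, from 9.3% to 19.1%, but stays
far behind — earlier calls help everywhere, yet cannot erase geography.

```r
gains <- compute_gains(tab)
gains[gains$name == "Tokke" & gains$delta_min == 5, ]
#> # A tibble: 1 × 5
#>   name  delta_min survival gain_pp gain_rel_pct
#>   <chr>     <dbl>    <dbl>   <dbl>        <dbl>
#> 1 Tokke         5    0.431    13.1         43.7
```

A five-minute-earlier call in mountainous Tokke is worth 13.1 percentage
points of survival. Monte Carlo bands and a full run:

```r
result <- run_analysis(cohort, t_grid = seq(0, 40, 1),
                       mc_cfg = mc_config(n_iter = 10000, noise_sigma = 0.02,
                                          seed = 1))
write_outputs(result$table, result$summaries, "out/")   # CSVs + run_metadata.json
replay_run("out/run_metadata.json")                     # reproduces the run exactly
```

A shell entry point with the same capabilities ships in `inst/cli/ohcasim`
(subcommands `table`, `curve`, `simulate`, `sensitivity`, `synth`); see
`?cli_main`.

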