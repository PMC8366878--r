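# rszentry

Quantifying spatial and temporal variation in an important component of
bird collision risk at wind energy facilities: the probability that an
eagle which approaches within 150 m of a turbine subsequently enters that
turbine's **rotor-swept zone** (RSZ) — the cylinder of air its blades
sweep. Facilities that practise *informed curtailment* shut a turbine down
only when a detected bird is judged to be at imminent risk; the curtailment
rule is usually uniform across the facility, even though some turbines and
some months are demonstrably riskier than others. `rszentry` turns 1-Hz 3D
flight tracks and a turbine table into per-approach binary entry outcomes,
fits a hierarchical Bayesian model of the entry probability per
turbine–month cell, and classifies each turbine, month and cell as safer
or riskier than the facility average.

## The model

Each approach *i* of a track within 150 m of turbine *t* in month *m* is a
Bernoulli trial: did any point of the track lie inside that turbine's
rotor-swept zone?

```
y_i ~ Bernoulli(p[t(i), m(i)])
logit p[t,m] = mu + alpha_t + beta_m + gamma_tm
alpha_t ~ N(0, sigma2_turbine)     # turbine main effect
beta_m  ~ N(0, sigma2_month)       # month main effect
gamma_tm ~ N(0, sigma2_cell)       # turbine-month interaction
```

with vague uniform priors on `mu` (over [-10, 10]) and on each variance
(over [0, 25]). The model is fitted by an adaptive random-walk
Metropolis-within-Gibbs sampler (three chains of 5,000 iterations, burn-in
500, thinning 2, by default), with Gelman–Rubin R̂ diagnostics.

The facility **reference average** is the overall entry probability
(entries / approaches), computed per posterior draw as the
approach-count-weighted mean of the cell probabilities. For every turbine,
month and cell, the **probability of direction** (pd) is the share of draws
in which the reference exceeds that quantity; pd > 0.95 flags it *safer*
than average, pd < 0.05 *riskier*.

Around the model sit the geometric pieces of the curtailment system:
cylinder construction from turbine specifications, point-in-cylinder and
ray–cylinder entry-time primitives, the inner-cylinder / time-to-collision
curtailment decision rule, and a synthetic-study generator (110 turbines,
11 months, ~10,000 approaches, 1-Hz tracks built to match known
entry labels) that makes the whole pipeline testable end to end.

## Worked example

```r
library(rszentry)

# a small synthetic facility: 12 turbines, 11 months, 1,200 approaches
study <- simulate_entry_study(sim_config(n_turbines = 12, n_siemens = 5,
                                         total_approaches = 1200), seed = 7)
data <- build_dataset(study$tracks, study$layout$turbines)
fit <- fit_entry_model(data, model_config(seed = 1))
fit
#> Bayesian turbine-month entry model
#>   1200 approaches, 318 entries (26.5%), 95 observed cells (12 turbines x 11 months)
#>   3 chains x 2250 kept draws (burn-in 500, thin 2)

tidy(fit)
#> # A tibble: 4 × 6
#>   term           estimate std.error   conf.low conf.high  rhat
#>   <chr>             <dbl>     <dbl>      <dbl>     <dbl> <dbl>
#> 1 mu              -1.19       0.217 -1.60         -0.748  1.00
#> 2 sigma2_turbine   0.360      0.366  0.0207        1.29   1.00
#> 3 sigma2_month     0.0819     0.113  0.0000897     0.355  1.00
#> 4 sigma2_cell      0.454      0.191  0.169         0.931  1.00

summ <- risk_summary(fit)
dplyr::filter(tibble::as_tibble(summ), scope == "turbine", class != "average")
#> # A tibble: 2 × 9
#>   scope   turbine_id month_key     n posterior_mean cri_low cri_high      pd class
#>   <chr>   <chr>      <chr>     <int>          <dbl>   <dbl>    <dbl>   <dbl> <chr>
#> 1 turbine T005       <NA>         90          0.415  0.304     0.536 0.00267 riskier
#> 2 turbine T009       <NA>         63          0.142  0.0693    0.231 0.996   safer
```

`mu` is the grand mean on the logit scale (here logit⁻¹(-1.19) ≈ 0.23,
near the 26.5% empirical rate), and the variance components say how much
turbines, months and their interaction spread around it — here turbines
and turbine–months vary, months barely do. Turbine T005 is flagged
riskier: in almost no posterior draw (pd = 0.003) is the facility average
above its mean entry probability of 0.415. `autoplot(summ)`,
`plot_risk_map(study$layout$turbines, summ)` and `plot_monthly_range(summ)`
draw the corresponding figures, and `headline_stats(summ)` collects the
extremal risk ratios and the posterior SD of cell probabilities.

A file-based pipeline (`run_pipeline()`, or `inst/cli/rszentry.R` from a
shell) chains the stages simulate → process → curtail → fit → summarize →
report, writing CSV/JSON artifacts and a GeoJSON risk map.

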