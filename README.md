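# succmib

Succession on degraded areas — former farmland, power-station ash heaps,
brown-coal mining heaps, managed forest soil — is slow, and managers need a
number that says *where on the trajectory* a site is. The Mean Individual
Biomass (MIB) of carabid beetles provides that number: MIB is the total
biomass of a pitfall-trap sample divided by the number of individuals
caught (mg), and it rises as large-bodied, late-successional species become
dominant. `succmib` is for ecologists and restoration practitioners who
collect such catches along chronosequences (sites of different stand age
standing in for one site through time) and want to quantify, compare and
forecast succession.

The core is a four-parameter **delayed logistic model** of the MIB
trajectory over stand age *a*. With model time *t = a − t₍delay₎*:

```
N(a) = N0                                    for t ≤ 0   (delay phase)
N(a) = K / (1 + ((K − N0)/N0) · e^(−rt))     for t > 0   (increase → stagnation)
```

the analytic solution of the logistic equation `dN/dt = r·N·(K − N)/K`
started at `N0`. The parameters are the *initial degradation level* `N0`
(mg), the *delay* `t_delay` (years), the *increase rate* `r` (1/years) and
the *recovery level* `K` (mg). The package computes MIB from catch tables,
tests the MIB–age trend (Spearman rank correlation, exact permutation
p-values for n ≤ 8), fits the four parameters to a series by profiled
nonlinear least squares with identifiability flags, ships the parameter
presets for five studied area types, and includes a seeded community
simulator whose expected MIB follows any prescribed trajectory — so the
whole pipeline is verifiable without field data.

## Worked example

Simulate a mining-heap chronosequence (4 sites aged 3–23 years, three
consecutive sampling years each, expected catch 200 individuals per
site-year), compute the MIB series, test the trend, and fit the model with
the initial level pinned at 40 mg:

```r
library(succmib)

d <- sim_design("mining_heap", preset_params("mining_heap"),
                base_ages = c(3, 10, 16, 23), seed = 7)
pool <- species_pool()
catches <- simulate_chronosequence(d, pool)
series <- build_mib_series(catches, pool_mass_table(pool))
spearman_mib_age(series)
#> # A tibble: 1 × 4
#>     rho  p_value     n method
#>   <dbl>    <dbl> <int> <chr>
#> 1 0.860 0.000332    12 t approximation

fit <- fit_succession(series, fix_initial = 40)
tidy(fit)
#> # A tibble: 4 × 4
#>   term     estimate fixed flagged
#>   <chr>       <dbl> <lgl> <lgl>
#> 1 initial    40     TRUE  FALSE
#> 2 delay      10     FALSE FALSE
#> 3 rate        0.601 FALSE FALSE
#> 4 recovery  205.    FALSE FALSE
```

The MIB–age correlation is strong and positive (ρ = 0.86, p < 0.001), and
the fit recovers the generating parameters — a 10-year delay, an increase
rate of 0.60/year against a true 0.6, and a recovery level of 205 mg
against a true 210 — from just 12 noisy points. `autoplot(fit)` overlays
the fitted curve on the series, drawing unreliable points (< 25
individuals) as open circles and unidentifiable curve segments dashed;
`predict(fit, ages = 0:120)` tabulates the trajectory with phase labels and
extrapolation flags.

A command-line entry point wraps the same functions for shell pipelines:

```sh
Rscript inst/cli/succmib.R simulate --preset mining_heap --seed 7 --out-dir runs/mh
Rscript inst/cli/succmib.R mib --catches runs/mh/catches.csv --masses runs/mh/masses.csv --out-dir runs/mh
Rscript inst/cli/succmib.R fit --series runs/mh/mib_series.csv --fix-n0 40 --out-dir runs/mh
```

## Vignette

`vignettes/succession-mib.Rmd` documents the model and its assumptions, the
fitting and identifiability conventions, what the simulator does and does
not emulate, and the package's numerical choices.
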