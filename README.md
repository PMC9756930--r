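# rrml — robust and resilient regression for scenario-based production forecasting

Production planners rarely hold one history: they hold several parallel
readings of it — a pessimistic, a plausible and an optimistic scenario,
each with a probability — and they need a single trend whose scenario
forecasts remain credible under disruption. `rrml` fits that trend by
minimizing the **RRMAD** (robust and resilient mean absolute deviation)
objective

```
RRMAD = β Σᵢ wᵢ Γ̄ᵢ + (1 − β) √(−2 ln α) Σᵢ wᵢ σ̄ᵢ
```

over the coefficients of a basis expansion `f(x) = Σₖ aₖ g(x)^(k−1)`,
where each scenario's forecast is the trend scaled by a resiliency
coefficient, `y′ᵢₛ = ρₛ f(xᵢ)`; `Γ̄ᵢ = Σₛ pₛ |y′ᵢₛ − yᵢₛ|` is the
probability-weighted mean absolute deviation in period `i`; `σ̄ᵢ` is the
probability-weighted spread of those deviations across scenarios; `wᵢ`
are recency/antiquity observation weights; `β` (conservativity) trades
accuracy against cross-scenario robustness and `α` (confidence level)
scales the dispersion penalty.

Both terms are piecewise-linear, so the fit is computed **exactly** as a
linear program: absolute values are split into nonnegative variable pairs
and the instance — `4|I||S|` nonnegative variables, `2|I| + 3|I||S| + |K| + 1`
free variables, `5|I||S| + 2|I| + 1` equality constraints, zero binaries —
is solved by a built-in two-phase revised simplex. Every reported
diagnostic is recomputed from the coefficients, never read off solver
variables. The package also provides scenario-weighted goodness of fit,
closed-form model-size accounting, polynomial and three sinusoidal basis
families, degree-scan / basis-comparison / sensitivity drivers, a
ground-truth synthetic generator, delimited-text IO, MPS export and a CLI.

## Worked example

```r
library(rrml)

s <- demo_production_series()   # synthetic 21x3 panel, labels 2001-2021
s
#> <scenario_series> 21 observations x 3 scenarios
#>   p   = 0.3333, 0.3333, 0.3333
#>   rho = 0.85, 0.9, 0.95
#>   labels: 2001 ... 2021
#>   y range: 59.908 .. 156.29

fit <- rrml_fit(s, rrml_profile("main"))   # beta=0.98, alpha=0.05, degree 7
fit
#> <rrml_fit> 21 obs x 3 scenarios, polynomial basis, 7 terms (optimal)
#>   RRMAD = 1.64948   R2 = 0.9914   tightness gap = 8.39e-13
#>   coefficients: 54.6795, 20.5503, -4.09943, 0.447759, -0.0253093, 0.000749561, -9.32236e-06
```

The fitted objective 1.649 is in production units (million tonnes): the
weighted mean absolute deviation plus the confidence-scaled dispersion
penalty. `R2 = 0.9914` is the probability-weighted coefficient of
determination across the three scenarios, and the tightness gap at 1e-13
certifies that the LP's absolute-value splitting was exact. Sensitivity of
the objective to the conservativity coefficient:

```r
param_sweep(s, rrml_profile("main"), "beta", c(0.95, 0.98, 1))
#> <rrml_sweep> parameter: beta (anchor rrmad 1.64948)
#>  setting rrmad variation_pct    r2 feasible  main
#>     0.95 1.667          1.09 0.991     TRUE FALSE
#>     0.98 1.649          0.00 0.991     TRUE  TRUE
#>        1 1.637         -0.73 0.991     TRUE FALSE
```

Lowering `β` to 0.95 (more weight on cross-scenario dispersion) raises the
objective by 1.09%; dropping the dispersion term (`β = 1`) lowers it by
0.73%. Scenario forecasts extend to future periods with the same
resiliency scaling:

```r
predict(fit, newx = 22:24)      # counters for 2022-2024
#>            s1       s2       s3
#> [1,] 142.4030 150.7797 159.1563
#> [2,] 143.1604 151.5816 160.0028
#> [3,] 141.3991 149.7167 158.0343
```

Own data come in through `read_series()` (wide `year,s1,s2,...` or long
`year,scenario,production` delimited text), and the same operations are
available from a shell via the CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rrml.R", package = "rrml"))')" \
    complexity --n-obs 21 --n-scen 3 --degree 7
#> binary 0
#> positive 252
#> free 239
#> constraints 358
```

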