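---
title: "Robust and resilient scenario regression: model, algorithm, design choices"
author: "rrml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust and resilient scenario regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrml)
```

## The model

A planner observes a production series under several parallel scenarios
(say pessimistic, plausible, optimistic), indexed `s = 1..|S|` with
probabilities `p_s`, over periods `i = 1..|I|`. The package fits one trend

    f(x) = sum_k a_k * g(x)^(k-1),   k = 1..|K|

and turns it into scenario forecasts through a per-scenario *resiliency
coefficient*, `y'_is = rho_s * f(x_i)`: a scenario with `rho_s = 0.85`
operates at 85% of trend capacity because of disruption. The coefficients
minimize the robust objective

    RRMAD = beta * sum_i w_i * Gbar_i
          + (1 - beta) * sqrt(-2 * log(alpha)) * sum_i w_i * sbar_i

where, with `G_is = |y'_is - y_is|`,

* `Gbar_i = sum_s p_s G_is` is the probability-weighted mean absolute
  deviation in period `i` — the accuracy term;
* `sbar_i = sum_s p_s |G_is - Gbar_i|` is the probability-weighted spread of
  those deviations across scenarios — the robustness term, penalizing fits
  that are accurate on average but erratic across scenarios;
* `w_i` are observation weights (below), and `beta` in `[0,1]` trades the
  two terms. The dispersion multiplier `sqrt(-2 log alpha)` grows as the
  confidence level `alpha` shrinks: at `alpha = 0.05` it is about 2.448, so
  `risk_coefficient(0.05, 0.95) ≈ 0.1224`.

Both terms are piecewise-linear in `a`, so the whole problem is solved
exactly as a linear program (no local minima, no step sizes).

### Observation weights

`observation_weights(lambda, n)` implements

    w_i = lambda * i / T + (1 - lambda) * (n - i + 1) / T,   T = n(n+1)/2,

which always sums to one. `lambda = 1` is a linear recency ramp, `lambda =
0` the reverse (old data dominate), and `lambda = 0.5` cancels to exactly
uniform `1/n`. Reversing the weight vector is the same as swapping `lambda`
for `1 - lambda`.

### Basis families

All four families are powers of a transformed regressor and therefore keep
the program linear: `g(x) = x` (polynomial), `sin(omega x)`,
`x sin(omega x)`, `x + sin(omega x)`. `omega` (radians per unit `x`) has no
default for the sinusoidal families — a silent default would smuggle in a
seasonality assumption — and must be supplied per run. The comparison
driver pins one conventional `omega` per family (`2*pi`, `4*pi`, `pi`):
full, half and double-unit cycles. Note that on integer counters
`sin(pi * x) = 0`, so the shifted-sine family with `omega = pi` coincides
with the polynomial one — a useful structural identity that the tests
exploit — while `omega = 2*pi` and `4*pi` annihilate the pure-sine and
`x sin` families on integer grids (they degenerate to a constant and their
comparison rows mostly document that degeneracy). Sinusoidal bases are only
informative when `omega` is incommensurate with the sampling grid.

### Regressor encoding

Internally the regressor is the observation counter `1..|I|`; calendar
years are display labels. This is deliberate: a seventh power of a calendar
year is around `10^23`, which destroys double-precision conditioning, while
counters keep the degree-7 basis solvable (see *Numerical choices*).
`x_scale = "raw"` and `"unit"` are available for users who want raw-year or
min–max–scaled encodings.

## The exact linear-programming reformulation

Each absolute value is split into a pair of nonnegative variables
(`u = va - vb`, `|u| = va + vb`), giving per cell `(i, s)` four nonnegative
split variables, free variables for the trend value, forecast, deviation,
period mean deviation, period dispersion, coefficients, and the objective
value, tied together by equality rows. The resulting instance has

* 0 binary variables (the model is a pure LP),
* `4 |I| |S|` nonnegative variables,
* `2|I| + 3|I||S| + |K| + 1` free variables,
* `5|I||S| + 2|I| + 1` equality constraints,

which `complexity_counts()` evaluates in closed form and the builder is
tested to match exactly — for the 21 x 3, degree-7 study shape: 252
nonnegative, 239 free, 358 constraints.

**Tightness.** Splitting is exact at the optimum only while the accuracy
cost dominates the dispersion cost; the sufficient condition implemented in
`tightness_holds()` is

    beta > 2 * (1 - beta) * sqrt(-2 log alpha) * max_s(1 - p_s).

At the anchor settings (`beta = 0.98`, `alpha = 0.05`, uniform `p` over
three scenarios) the right-hand side is about 0.163, so the condition holds
with a wide margin. Because it *can* fail (small `beta`), `rrml_fit()`
recomputes every diagnostic from the coefficients via `rrmad_evaluate()`
and reports the largest discrepancy between the LP's deviation variables
and the recomputed `|y' - y|` as `tightness_gap`; outside the tightness
regime it additionally warns that the LP value is a lower bound. A related
subtlety: the direct objective is convex in `a` exactly when the tightness
condition holds (it then equals the partial minimum of the jointly convex
LP); outside that regime the dispersion term is a difference-of-convex
construct and convexity can genuinely fail, which is why the convexity
property test draws its configurations from the tightness regime.

**Multiple optima.** Absolute-deviation fits can be non-unique. The solver
returns one vertex solution; tests compare objective values, never
coefficients, except under noiseless recovery where the representation is
unique by construction.

## Solver

No general-purpose LP package is available in the package's dependency
set, so `solve_lp()` implements a dense two-phase revised simplex: free
variables are split internally, phase 1 certifies feasibility from an
artificial basis, residual artificials are pivoted out (rows that cannot be
pivoted are redundant and stay inert), and phase 2 bars artificial columns
from re-entering. The basis inverse is maintained by elementary updates and
refactorized every 150 iterations; Dantzig pricing switches to Bland's rule
after a long degenerate stall, so termination is guaranteed. The solver
never reports a non-optimal point as optimal: statuses are `optimal`,
`infeasible`, `unbounded`, `numerically-failed`. `quantreg` — which solves
the pure weighted-LAD special case (`beta = 1`, one scenario) but not the
scenario-dispersion objective — serves as an independent cross-check in the
test suite, agreeing with the LP to 1e-8; tiny instances are additionally
verified against dense coefficient grid search and an enumeration oracle
for the weighted-median case.

## Numerical choices

* **Basis preconditioning.** Raw degree-7 power bases on counters `1..21`
  have condition number about `5.8e8`; the builder therefore orthonormalizes
  the basis columns (QR) inside the program and maps the solved coefficients
  back through the triangular factor. This is a pure change of variables:
  counts, feasible set and optimum are untouched, but pivot tolerances
  become meaningful. Without it the simplex stalls at degree 7.
* **Equilibration.** The standardized matrix is row/column max-equilibrated
  (two passes) before solving.
* **Tolerances.** Pivot/optimality tolerance `1e-9` (relative); all
  post-hoc identity checks at `1e-6` relative, which is what the basis
  conditioning supports in double precision.
* **Stability flag in the degree scan.** An equality-form LP of this shape
  is never infeasible in the strict sense, yet very high degrees are not
  trustworthy. A scan row is flagged not feasible when the solver fails
  *or* the raw basis matrix condition number exceeds
  `1e-6 / .Machine$double.eps` (about `4.5e9`) — the point at which a
  forward error of order `kappa * eps` can no longer stay below the 1e-6
  diagnostic tolerance, so reported raw coefficients would carry no
  certifiable digits. On the 21-observation counter grid this passes
  degree 7 (`kappa ≈ 5.8e8`) and flags degree 8 (`kappa ≈ 2.0e10`).
* **Degenerate inputs.** Zero scenario probabilities are legal (the
  dispersion of the surviving scenario collapses to zero and the problem
  reduces to its weighted LAD); a constant observed scenario makes R²
  undefined and is signalled, not silently clipped; `|I| < |K|` is allowed
  and noted as interpolation-capable.

## Goodness of fit

`scenario_r2()` computes, per scenario, `RS_s² = 1 - SSE_s / SST_s` with
the total sum of squares about that scenario's own mean — the only reading
under which a perfect fit scores exactly 1 — and aggregates by
`sum_s p_s RS_s²`. The aggregate is bounded above by 1 but *not* clipped
below: badly misspecified fits can drive it below -1, and the package
reports that honestly rather than masking a diagnostic.

## The synthetic generator and what it does (not) show

`generate_series()` produces panels with known ground truth: a basis trend
on counters, scenario structure either by the model's own resiliency
scaling (`y_is = rho_s f(x_i) + noise`, the default, matching the model's
generative reading) or by a symmetric percentage band around the base trend
(the pessimistic/plausible/optimistic reading); noise is additive-normal,
multiplicative-normal (default 2% — the visual scale of year-to-year
variation in national production series), or absent. Identical
specifications and seeds reproduce identical panels, and the caller's RNG
state is untouched.

`demo_production_series()` is a fixed synthetic fixture with the study
shape used throughout the documentation: 21 periods labelled 2001–2021,
three scenarios, `rho = (0.85, 0.90, 0.95)`, uniform probabilities, and a
smooth seven-term trend on the scale of a national agri-food output series
(about 70–170 million tonnes). It exists so that every driver can run
end-to-end without any external data; real deposited case data can be
supplied through `read_series()` and run under `rrml_profile("main")`.

Passing tests on generated data demonstrate correctness of the
*optimization and accounting* — recovery of known coefficients, exactness
of the linearization, dominance over least-squares candidates, convergence
of the pure-noise objective to the half-normal mean `sigma * sqrt(2/pi)`.
They do not validate the modelling assumptions on real data: real series
have serial dependence, non-normal shocks and scenario constructions that
no generator setting reproduces.

## Parameter profiles and experiment drivers

Two named profiles ship: `"main"` (`beta = 0.98`, `alpha = 0.05`,
`lambda = 0.5`, degree 7, polynomial, counters) — the anchor configuration
for all sensitivity variations — and `"elicited"` (`beta = 0.95`, with
`omega = 2*pi/12` recorded for sinusoidal runs), the parameter set as
originally elicited from sector managers. The drivers are pure functions of
their inputs: `degree_scan()` (selects the smallest degree within `1e-3` of
the best feasible objective), `compare_basis()` (variation against the
polynomial anchor), and `param_sweep()` over `beta`, `alpha`, `lambda`,
whole resiliency vectors, or probability vectors (which also reports the R²
variation, since reweighting scenarios moves both objective and fit
quality). Default sweep grids mirror the study design: `beta` 0.95–1,
`alpha` 1–5%, `lambda` 0–1, 5-point whole-vector resiliency shifts, and
probability mass progressively concentrated on the middle scenario.
Exported tables round half-even to 3 decimals (values) and 2 decimals
(percentages), with a full-precision companion file.

## Problem sizes used in the checks

The test-suite and acceptance-script runs use: the 21 x 3 degree-7 fixture
for end-to-end drivers; 8–15 observation random instances (20 of them) for
the exactness/dominance properties; 3–4 observation instances for grid
search; 150 observations for the half-normal convergence check with a
10⁴-draw Monte-Carlo oracle; and 100 random dimension triples for the
count identities. These sizes were chosen so the whole battery solves a few
dozen LPs in a couple of minutes while leaving each check statistically
meaningful.

## Known limitations

* The dense simplex targets instances up to a few hundred observations;
  beyond that a sparse or interior-point backend would be needed (the
  `solve_lp()` contract is deliberately solver-agnostic, and `write_mps()`
  exports any built instance for external solvers).
* `rho` is applied identically in-sample and when extrapolating to future
  periods; the model offers no basis for treating them differently.
* No automatic `omega` estimation, no basis families beyond the four
  implemented, no integer variables, and no tail-risk (CVaR-type)
  objective variants.
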