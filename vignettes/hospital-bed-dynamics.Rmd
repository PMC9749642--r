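---
title: "Modelling hospital-bed shortage with stock-flow dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hospital-bed shortage with stock-flow dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedflow)
```

## The model

`bedflow` simulates the supply of and demand for hospital beds in a city
as a deterministic stock-flow system. Four stocks accumulate over time:

* **population** (persons), growing exogenously at a constant fractional
  rate;
* **number_of_bed** (beds), grown endogenously by construction;
* **number_of_specialist_physicians** (specialists), whose presence
  attracts patients travelling in from surrounding regions;
* **capacity_of_home_care_services** (service-days/year), an
  out-of-hospital care channel that substitutes for bed-days.

Demand is assembled each instant from algebraic auxiliaries:

$$
\begin{aligned}
\text{total patients} &= \text{travelers} + \text{population}\times r_p,
  \qquad \text{travelers} = \text{specialists}\times r_t\\
\text{bed-days required} &= \text{total patients}\times \text{LOS},
  \qquad \text{bed-days supplied} = \text{beds}\times 365\\
\text{occupied bed-days} &= \min(\text{required},\;
  \rho^\ast\times\text{supplied})\\
\text{shortage} &= \max(0,\; \text{required} -
  \rho^\ast\times\text{supplied})
\end{aligned}
$$

with $r_p$ the patient-to-population ratio (0.129 patients/person/year
by default), $r_t$ the travelers-to-specialists ratio, LOS the average
length of stay in days, and $\rho^\ast = 0.85$ the optimal occupancy
rate. Two consequences of this algebra are checked throughout the test
suite: occupancy never exceeds $\rho^\ast$, and a positive shortage
occurs exactly when occupancy is pinned at $\rho^\ast$.

Supply responds to pressure through four piecewise-linear lookup
tables ("rate effects"), the standard system-dynamics device for
empirically shaped nonlinearities:

| table | driver (x) | effect (y) | shape |
|-------|-----------|------------|-------|
| F1 | bed occupancy rate | fractional growth of home-care capacity (/yr) | non-decreasing |
| F2 | specialist-to-bed ratio | fractional growth of specialists (/yr) | non-increasing |
| F3 | bed-to-patient ratio | fractional growth of beds (/yr) | non-increasing |
| F4 | home-care share (home-care days / total bed-days) | multiplier on the base LOS | non-increasing, F4(0) = 1 |

Each capacity stock grows as `stock × rate_effect` — the conventional
fractional-growth closure for rates that are described as "rates of
increase" driven by ratios. This closure makes the three feedback
loops carry their intended polarities:

* **B2 (balancing)** — scarce beds per patient raise F3, construction
  accelerates, occupancy and shortage fall back;
* **B1 (balancing)** — high occupancy raises F1, home-care capacity
  grows, the home-care share rises, F4 shortens stays, occupancy falls;
* **R1 (reinforcing)** — more patients bring more beds, more beds
  bring more specialists (F2), specialists attract travelling
  patients, which adds demand.

Sign tests for all three loops, run with only the relevant tables
active, are part of the acceptance suite.

## Numerical scheme

Integration is explicit Euler with a fixed step, the convention of the
graphical system-dynamics tools this model class comes from; the stock
update *is* the difference equation, so a one-stock linear model
reproduces compound growth $x_0(1+g\,dt)^{t/dt}$ to machine precision
(an engine-level test asserts $10^{-12}$ relative). The default step
is `dt = 1/12` year: shortage onsets are reported at sub-annual
resolution, and saved output defaults to the same grid. The horizon is
2015–2035, i.e. twenty years of integration starting from 2015 initial
stocks.

Other numerical conventions:

* equations are parsed expression trees over a closed builtin set
  (arithmetic, comparisons, `IF_THEN_ELSE`, `MAX`, `MIN`, `RAMP`,
  `STEP`, lookup application, `TIME`) — configurations are data, never
  host-language code;
* any division with an exactly zero denominator evaluates to 0 and
  warns once per run naming the variable, so extreme-condition tests
  (zero beds, zero patients) remain runnable;
* `saveper` must be an integer multiple of `dt` (relative tolerance
  $10^{-9}$), and both must divide the horizon;
* lookup evaluation clamps exactly to the endpoint ordinates outside
  the breakpoint domain;
* runs are pure functions of the configuration: repeated calls are
  bit-identical, which the reporting layer exploits for byte-level
  determinism checks.

## Scenarios and policies

Scenarios are exogenous-environment assumptions; policies are decision
levers. Both act from 2020, the first year after the 2015–2019
historical window the model treats as observed.

* `S1` status quo; `S2` continued population growth plus aging ramps
  (patient ratio +0.002/yr, base LOS +0.05 days/yr in the shipped
  presets); `S3` reduced growth proportion (0.007 after 2020) with the
  same aging ramps; `S4` as `S2` with the travelers ratio declining
  (−1.5/yr), reflecting a more equitable regional distribution of
  physicians. The preset magnitudes are this package's synthetic
  assumptions — they are configuration entries, trivially overridable.
* `P1` no intervention; `P2` beds only; `P3` home care only; `P4`
  both. Interventions are constant additional annual inflows (not
  one-time jumps), which keeps each lever one-dimensional and produces
  smooth trajectories.

`solve_min_intervention()` finds the smallest lever value that keeps
peak shortage at or below `tol` (default 1 bed-day/yr) by bisection,
after verifying a bracket (upper bound ten times the initial stock
spread over the horizon, doubled up to three times) and asserting that
peak shortage responds monotonically to the lever — a non-monotone
response aborts the solve rather than returning a meaningless root.

For `P4` the two levers must be traded off, and no canonical rule
exists. The package minimizes the bed addition — beds being by far the
more expensive resource — over a grid of home-care additions capped at
half the `P3` (home-care-only) solution, tie-breaking toward less home
care. The cap encodes the judgement that home-care expansion cannot be
relied on without limit as the sole remedy; without it the bed-minimal
choice degenerates to exactly `P3` and the mixed policy would never
contain beds at all. With the cap, `P4` always uses strictly positive
amounts of both levers and never more beds than `P2` (`P2` is the
`h = 0` column of the same program).

## Validation toolkit

* `compare_to_history()` aligns a run with annual observations and
  reports MAPE and RMSE per variable. The shipped validation gate is
  MAPE ≤ 10% per variable on the synthetic-history fixture — an
  artifact convention chosen to flag gross miscalibration, not an
  empirical claim.
* `extreme_condition_suite()` runs marginal-limit checks: no
  residents ⇒ all patients are travelers; no patient sources ⇒ no
  shortage ever; a thousandfold bed stock ⇒ near-zero occupancy and no
  shortage; zero base LOS ⇒ zero bed-days required.
* `equilibrium_test()` switches off growth and all rate effects and
  requires every stock to hold its value to $10^{-9}$ relative drift,
  at any `dt`.
* `recover_lookup_slopes()` fits the free ordinates of one lookup
  table by nested-simulation least squares (sum of squared errors,
  each variable scaled by its mean observation). Monotonicity is
  enforced by reparameterization — the free vector is the first
  ordinate plus signed squared increments — and the optimizer is
  Nelder-Mead with a simplex restart, because the objective is cheap
  but non-smooth where the occupancy cap engages. Ordinates to which
  the objective is insensitive (an inert loop, or breakpoints the
  trajectory never approaches) are reported as under-determined
  rather than returned as if identified.

## The synthetic-data generator

The study system's calibration inputs (registry extracts; the
expert-elicited lookup tables; the travelers ratio and base LOS) are
not public, so `gen_config()` generates complete, internally coherent
stand-ins. Printed reference values are kept exactly: population
1,557,600; 3560 beds; 690 specialists; 76,650 home-care service-days;
growth proportion 0.014; patient ratio 0.129; optimal occupancy 85%.
The two site-specific parameters default to synthetic placeholders
(travelers ratio 60/specialist/yr, base LOS 3.5 days), chosen once so
that the `baseline_shortage` archetype shows a shortage onset in the
middle of the horizon under the status quo — about year 11 with the
frozen fixture seed (2015) — and earlier under the environmental
scenarios. They are labelled synthetic everywhere and are not
estimates of any real facility.

Archetypes: `inert` switches every feedback off (the equilibrium and
solver-oracle workhorse); `baseline_shortage` is the default fixture;
`early_shortage` starts demand near capacity. The seed applies a small
multiplicative jitter to the lookup ordinates (shape constraints
preserved), so randomized property suites can draw many distinct valid
configurations deterministically.

`gen_history()` simulates the 2015–2019 window noiselessly and applies
multiplicative lognormal observation noise, `exp(N(0, noise_sd))`,
default `noise_sd = 0.05`: registry counts are positive and their
errors roughly proportional, which the test suite verifies against the
lognormal mean $e^{\sigma^2/2}$ by Monte Carlo.

What the generator deliberately does **not** emulate: pandemic-era
disruption of occupancy and admissions, age-structured demand, bed
decommissioning or specialist attrition (the model is inflow-only, as
the equation set implies), and cost accounting. Passing tests on
synthetic data therefore demonstrate that the machinery — simulation,
solvers, calibration — is correct and internally consistent, not that
the shipped numbers forecast any real city.

## Problem sizes used in the shipped checks

The randomized structural suite runs 200 configurations over a
ten-year horizon at monthly steps; the solver oracle scans bed
additions at 0.01 beds/yr resolution on a quarterly-step toy; lookup
recovery fits three free ordinates against twenty-one annual
observations, with twenty noise replicates at `noise_sd = 0.02`; the
full experiment sweep solves ten minimal interventions and runs all
sixteen scenario-policy cells at monthly steps. These sizes were
chosen to exercise every code path at full fidelity while keeping a
complete check of the package comfortably interactive.

## Known limitations

* Euler with `dt = 1/12` is first-order accurate; the model's rates
  are small (at most ~0.2/yr), so the discretization error is well
  below the uncertainty in any input, but stiff extensions would need
  a smaller step (higher-order integrators are out of scope).
* The inflow closure (`stock × rate effect`) and the home-care
  coupling (`LOS = base LOS × F4(share)`) are structural choices the
  equation set does not uniquely determine; both are documented here
  precisely because alternatives (e.g. additive inflows, occupancy-
  driven LOS) would change policy magnitudes while preserving loop
  polarities.
* Home-care capacity is interpreted as service-days per year, making
  the home-care share dimensionless; if it were patients per year the
  `F4` driver would need a per-patient conversion.
* The minimal-intervention search assumes a monotone shortage
  response; it verifies this on the solved axis and aborts otherwise,
  but it does not attempt global optimization over non-monotone
  responses.
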