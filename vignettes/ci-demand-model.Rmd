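---
title: "The cidemand model: assumptions, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cidemand model: assumptions, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidemand)
```

# The model

`cidemand` is a deterministic, aggregate stock-and-flow (System Dynamics)
model of cochlear implant (CI) demand and payer cost. The state is a person
count over single years of age (0..100) and four disease stages: healthy,
CI-relevant hearing loss, unilateral CI, bilateral CI. Children are assumed
fully hearing: stages 2–4 are structurally empty below age 20, and all
epidemiological and supply schedules are zero there.

One simulated day applies, in order, fertility, mortality, hearing-loss
incidence, unilateral implantation and sequential bilateral implantation,
each as a proportional outflow of its donor compartment; speech-processor
exchanges and reimplantations are computed from the implanted stock without
moving anyone between stages; and every 365th day the whole population shifts
one year of age. One simulated year is 365 such days followed by the cohort
shift; the year's accumulated flows are then priced.

Key structural assumptions, stated once:

* **Hearing loss is nonlethal and irreversible.** Mortality does not differ
  by stage, and there is no remission or hearing-aid pathway out of stage 2.
* **Stage flows only move forward** (healthy → hearing loss → unilateral →
  bilateral). Explantation without reimplantation is out of scope.
* **No migration and no sex dimension.** Fertility is births per *person* of
  age 15–49 per year, so a conventional per-woman total fertility rate must
  be halved when building inputs.
* **Device turnover is continuous.** Processors turn over at
  `(P3 + 2·P4)/l_s` per year and implants at `(P3 + 2·P4)/l_i`
  (bilateral users carry two devices). There is no per-device age tracking,
  so replacement flows respond instantly and exactly inversely to lifespan
  changes — which is also what makes the lifespan scenario contrasts
  analytic: changing `l_i` from 20 to 23 years reduces reimplantations by
  exactly `1 − 20/23 = 13.04%` on any demography, because replacement flows
  never feed back into the compartments.

# Incidence from grouped prevalence

Published hearing-loss prevalence comes in decade age classes.
`fit_prevalence()` fits `p(age) = a·exp(b·age)` to the class values by
nonlinear ordinary least squares (Levenberg–Marquardt, started from the
log-linear regression), using class midpoints as abscissae; an open-ended top
class is represented by its lower bound + 5 years. `incidence_from_prevalence()`
then takes the annual incidence at age `a` as the first derivative
`a·b·exp(b·age)`, clipped to [0, 1] and to zero below age 20.

Two caveats are intentional properties of this construction rather than bugs:

* The derivative rule ignores differential mortality and remission, so it
  understates true incidence at ages where mortality is high. It is used
  because it is the standard minimal back-calculation when only a prevalence
  cross-section is available.
* Incidence applies to the *healthy* stock only. As a cohort's healthy pool
  depletes, realized population incidence falls below the schedule; no
  renormalization is attempted.

The severity threshold (60 dB HL for the CI indication, 40 dB HL for the
relaxed-indication scenario) is simply a property of the prevalence table:
the relaxed scenario is the same model run on the moderate-loss table.

# Parameters and defaults

| Parameter | Unit | Default | Where it comes from |
|---|---|---|---|
| willingness `w` (baseline) | proportion/yr | 0.01 | calibrated so simulated implantations match observed national counts; the surveyed willingness profile (13–73%) is used only in scenarios |
| feasibility `fe_u`, `fe_b` | proportion/yr | survey table, 27–83% by decade | ENT-physician survey; decreasing in age |
| implant lifespan `l_i` | years | 20 (23 innovative) | device literature / expert panel |
| processor lifespan `l_s` | years | 5 | device literature |
| unit costs | € | 33,442.86 / 3,369.96 / 620.73 / 27,449.19 / 9,847.02 | baseline care cost schedule (first year, second year, year 3+, reimplantation, processor); an innovative-implant variant (37,578.71 / 3,310.69 / 602.21 / 31,777.68) prices the coated device |
| horizon | years | 40 | strategic planning window |
| step | days | 1 | native System Dynamics resolution |

Costs are nominal euro, constant over the horizon, and undiscounted — the
output is a budget-impact series, not a present-value evaluation.

## Cost bookkeeping

The unit-cost schedule distinguishes the first and second year after an
implantation event from the flat per-patient follow-up from year 3 until
death. The model keeps an event ledger of the current and previous year's
implantations: first-year cost prices this year's events; second-year cost
prices last year's events decremented by one year of age-specific survival;
the year-3+ cost prices the implanted stock (each patient once, bilateral
patients not double-counted) minus those two recent event cohorts. Bilateral
(second-ear) events are priced with the same schedule as first implantations,
and follow-up from year 3 is per patient, not per ear — a deliberate reading
of "per patient until death" that is worth a sensitivity run if it matters
for an application.

# Scenarios and ramps

`build_scenario()` bundles the named presets; everything is an override on
the shared inputs, so any combination can also be assembled with
`scenario()`. Time ramps are evaluated once per simulated year (a step
function at year boundaries): daily interpolation changes results by less
than the model's other O(dt) effects and yearly evaluation keeps runs exactly
reproducible.

A ramp from `v0` to `v_end` over `s` years is standard linear interpolation
`v0 + (v_end − v0)·t/s`. An alternative multiplicative form
`v0·(1 + (v_end − v0)/s·t)` — which reaches `v_end` at `t = s` only when
`v0 = 1` — is available via `ramp_spec(compat = TRUE)` (CLI:
`compat_ramp: true`). The distinction matters enormously for the willingness
ramp: starting from 0.01, the linear form reaches the surveyed profile at the
horizon (a ~50-fold increase), while the multiplicative form barely moves
(to ~0.017). Scenario intents here are stated as endpoint values ("reach a
30-year lifespan", "willingness reaches the surveyed values"), so the linear
form is the default; the compat switch exists to reproduce the much flatter
trajectories the multiplicative reading produces.

Feasibility multipliers and ramped willingness are capped at 1.0 after
application; every capping event is counted (`cap_events` attribute) and
reported, since capping silently bends a nominally linear scenario.

# Sensitivity and calibration

`tornado()` scales one parameter at a time by ±25% (feasibility, willingness,
and each of the five unit costs) and compares cumulative total cost against
the shared baseline run. Unit-cost parameters enter their component linearly,
so their bars are exactly ±25% of that component. Results are ranked by
tornado bar width (`|high − low|`), the usual convention for tornado
diagrams. Ranking by the single largest deviation would tie willingness and
feasibility exactly — scaling either *down* by 25% multiplies the implant
flows by the same 0.75, giving bit-identical runs — whereas bar width
separates them honestly: the willingness bar is longer because up-scaled
feasibility hits the cap at 1.0. That is also why willingness ranks first and
feasibility second on the stylized fixture.

`calibrate_willingness()` finds the uniform willingness scalar (or, in
`"scaled"` mode, the multiplier on the surveyed age profile) minimizing the
squared error between simulated and observed annual unilateral implantations.
Simulated implantations are monotone non-decreasing in the scalar, so the
objective is unimodal and Brent search on [0, 1] to a tolerance of 1e-6
suffices; an explicit squared-error objective replaces the informal "matches
current implantation numbers" criterion that motivated the baseline value of
0.01.

# The stylized country

`make_stylized_country()` generates all inputs in code, so every stage of the
pipeline is testable without any data download. It emulates, qualitatively, a
Western European demographic and epidemiological situation:

* an age pyramid with a late-middle-age (baby-boom) bulge, attenuated by
  survivorship to the current age so the initial old-age counts are
  consistent with the mortality schedule — without this, the old population
  would *shrink* as the bulge ages, inverting the model's central dynamic;
* sub-replacement fertility (0.75 lifetime births per person ≈ TFR 1.5),
  concentrated around age 30;
* Gompertz mortality `m(a) = 1.6e-5·exp(0.11·a)` (≈ 0.1 at age 80), capped at
  1 and forced to ≥ 0.5 at the absorbing top age so the 100+ bin drains;
* exponential prevalence curves `2e-4·exp(0.075·age)` (severe, > 60 dB HL)
  and `1e-3·exp(0.075·age)` (moderate, > 40 dB HL), the moderate table
  pointwise above the severe one by construction;
* the surveyed feasibility/willingness tables, bundled verbatim.

`german_like_spec()` additionally seeds base-year CI user stocks (4% / 3% of
the hearing-loss stock with unilateral / bilateral CIs), allocated across
ages proportional to the hearing-loss stock weighted by feasibility ×
willingness — the model gives no account of how existing users are
distributed, so the allocation rule places them where implantation would
have. With these stocks, processor exchange is the largest cost component
from the first simulated year, as in current care; without them, replacement
flows start from zero and first-implantation cost dominates early years.

What the fixture does **not** emulate: migration, sex structure, cohort
trends in fertility/mortality (rates are frozen at their base-year values),
hearing-aid use, and the absolute scale of a real country (it has 10^6
people; all flows and costs scale linearly in population size). Tests passing
on the fixture therefore validate the mechanics and invariants of the model,
not any real-world forecast: headline euro totals for an actual country
require that country's demography and prevalence as inputs via
`load_age_table()`.

# Numerical choices

* **Rate conversion.** Annual rates are scaled proportionally to the daily
  step (`rate/365`), the System Dynamics convention; it makes the daily loop
  match annual closed forms exactly for single flows, which the test suite
  exploits. Exponential compounding (`1 − (1 − m)^(dt/365)`) is available for
  mortality for users who prefer probability semantics.
* **Update order** within a day is fertility → mortality → incidence →
  unilateral → bilateral, applied sequentially. Order effects are O(dt) and
  bounded by the daily-vs-annual oracle test (0.5% per cell on a toy
  population over one year).
* **Aging** is a synchronized whole-cohort shift every 365 days, not a
  continuous 1/365-per-day leak; age 100 is absorbing under aging and drains
  only through mortality (hence the fixture's high top-age mortality).
* **Degenerate fits.** Exactly flat prevalence data produce a log-linear
  start slope of ~1e-17, which underflows the NLS machinery's relative-step
  numeric gradient; start slopes below 1e-10 are snapped to exactly 0. A
  fitted negative slope yields a negative incidence derivative, which is
  clipped to zero with a warning.
* **Ties** in the cumulative cost-component ranking are broken by the fixed
  component order (first-year unilateral, first-year bilateral, second year,
  subsequent years, reimplant, processor).
* **Problem sizes in the tests.** The suite runs the full 40-year horizon
  only where a result is horizon-dependent; scenario-contrast and property
  tests use 5–20-year horizons and a 10^6-person fixture, which exercise
  every code path at identical per-cell arithmetic.

# Limitations

Beyond the structural assumptions above: the incidence back-calculation
inherits any bias in the source prevalence; willingness is a single behavioral
catch-all calibrated to observed counts rather than a mechanistic quantity;
scenario changes apply from the first simulated year (no delayed adoption);
and costs exclude indirect, household and provider costs as well as inflation
and discounting. Results should be read as strategic orders of magnitude
under explicit assumptions, not point forecasts.
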