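---
title: "A bioeconomic cohort model for late-stage emerald ash borer management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bioeconomic cohort model for late-stage emerald ash borer management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eabsim)
```

## The problem

Two decades after the emerald ash borer (EAB, *Agrilus planipennis*) arrives
in a city, the management question changes. The large-scale removals are
done; what remains is a remnant population of ash (*Fraxinus*) trees kept
alive by biennial trunk injections of systemic insecticide (TreeAzin), at a
recurring cost, with the trees slowly declining anyway. Should a city keep
injecting in perpetuity, wind the program down and let the ash die, remove
the survivors preemptively, and how should replanting be scheduled?
`eabsim` is a deterministic, population-level bioeconomic simulator built to
answer that question for a remnant population of 1,490 city-owned ash
trees, and to rank seven candidate management options against five explicit
objectives (tree count, basal area, ash preservation, cost reduction, value
maximization).

## The demographic model

The population is represented as cohorts: groups of identically
parameterized trees carrying a count, a median DBH (diameter at breast
height, cm), a species class (ash / non-ash), an injection status, and — for
planted trees — a planting year. The model advances in annual timesteps over
a 20-year horizon. Each cohort-year:

* DBH grows by a fixed increment (ash 0.3 cm/yr, reflecting the reduced
  growth of long-injected trees; non-ash 0.47 cm/yr), including the planting
  year of a new cohort.
* The count is multiplied by a survival fraction and **rounded up**
  (`ceil`). Survival is 1 − 0.028 for injected ash, 1 − 0.20 for uninjected
  ash under late-stage EAB pressure, an empirical post-planting schedule
  (0.915, 0.883, 0.958, 0.939) for the first four years of a planted
  cohort, and 1 − 0.0085 (background mortality) thereafter.

The ceiling convention is load-bearing: it is the unique rounding rule
(ceiling, applied at *every* cohort-year transition) that reproduces the
published integer trajectories — 1490 → 1192 → 954 → 764 → 612 → 490 under
20 %/yr mortality, and 1490 → 1449 → … → 852 under 2.8 %/yr. Floor or
nearest rounding diverge within a few years. A property test checks that
the deterministic recurrence stays within sampling error of a per-tree
Bernoulli micro-simulation, which is what it approximates.

### The calibrated initial DBH

The initial median ash DBH is not stated anywhere; only Year-1 basal areas
are printed. `calibrate_initial_dbh()` inverts the basal-area identity
`pi * ((d0 + growth)/2)^2 * count / 1000 = printed basal` at Year 1
(707.0 printed units over 1,192 trees), giving **d0 = 27.181 cm**, which the
package ships as the default. With this single constant, every printed ash
basal value at Years 1–20 is reproduced to the printed 0.1 precision.
(At Year 1 of the injection scenarios the reproduction is 859.5 vs 859.4 —
a fourth-decimal sensitivity of the calibration constant; Years 5–20 agree
exactly.)

Basal area is reported in the printed unit of the source tables, which we
read as total trunk cross-sectional area in cm² divided by 1,000 (the
tables' "per 1000 m^3" label is dimensionally inconsistent; cm²/1000
reproduces every printed value).

## The seven scenarios

`builtin_scenarios()` encodes the management options declaratively:

| Slug | Injection | Preemptive removal | Replanting |
|---|---|---|---|
| `control` | never | — | none |
| `remove_replant` | never | — | match deaths, 1-yr lag |
| `preemptive_replant` | never | 400/yr from Yr 1 | match removals, same year |
| `replant_inject_remove` | Yrs 1–5 | 400/yr from Yr 6 | proactive 400/yr, cap 1,490 |
| `inject_remove_replant` | Yrs 1–5 | 400/yr from Yr 6 | match losses, same year |
| `perpetuity` | always | — | none |
| `perpetuity_replant` | always | — | match deaths, same year |

Conventions that the printed trajectories force:

* **Removal start Year 6.** "Injected for 5 yr then removed" is interpreted
  as removals beginning the year *after* the fifth injection year, because
  the tables print 1,295 living ash at Year 5.
* **Preemptive removal supersedes mortality.** In removal years the
  scheduled removal count is taken without applying EAB mortality (the
  dying trees are assumed to be among those removed): Year 1 of the
  preemptive scenario prints 1,090 = 1,490 − 400 exactly.
* **Replanting lag differs by scenario.** The printed Year-1 non-ash counts
  (0 vs 38 vs 366) imply same-year matched replanting in the injection and
  preemptive scenarios but a one-year lag in "Remove Dead Ash then
  Replant". Both conventions are exposed on `scenario_spec()`.
* **Proactive planting cap.** The printed non-ash counts of "Replant,
  Inject, then Preemptive Removal" (1,399 at Year 5, flat 1,480 late) are
  not reproducible under any natural planting cap we tried; the package
  plants 400/yr capped at the initial ash count (the stated 1:1 replacement
  ratio) and does not assert that scenario's non-ash counts.

## Economics

Annual management cost is the sum of removal (stumping included — no
separate schedule exists), pruning (a 4-year cycle: one quarter of all
living trees per year, priced by DBH bracket), injection (a 2-year cycle:
half of the injected population per year at $3.325/cm), and planting
($849.91 per scheduled tree). Standing-tree value uses the CTLA trunk
formula `(DBH/2)^2 * pi * NT * TC * FL * EL` with NT = $4.50/cm², ash
ratings 0.50 × 0.75 × 0.10 and non-ash 0.75 × 0.75 × 0.90. Dollar flows in
year *t* are inflated and discounted end-of-year by `(1.02 / 1.0283)^t`
(so Year-1 costs carry t = 1; the alternative t = 0 convention is
unstated in the source and changes nothing qualitative).

Three conventions deserve emphasis:

* **Replacement of dead planted trees is a cost-only event** confined to
  the four post-planting years that the survivability data cover: deaths in
  warranty years 1–2 are replaced free by the contractor, deaths in
  post-warranty years 3–4 are charged the full planting cost, and deaths
  from year 5 onward are ordinary background losses with no replacement
  charge. Replacements never add trees (the printed non-ash counts decline
  according to the raw survival rates). Restricting the charge to the
  tracked window is also the reading under which the published sensitivity
  result — cumulative discounted cost lowest at the highest removal rate —
  holds; charging every death forever makes the cost curve flat in the
  removal rate.
* **Removal/stumping charges apply to ash** (dead and preemptively
  removed); dead non-ash generate replacement-cost events only.
* **The published dollar tables are not reproducible** from the printed
  conventions: back-calculating the Year-1 CTLA value of the control
  scenario implies an effective ratings product of ≈ 0.84, not the stated
  0.5 × 0.75 × 0.10 = 0.0375. The package implements the formula exactly as
  printed, exposes all ratings in configuration, and asserts only
  *structural* cost properties (cumulative discounted cost non-decreasing;
  the control is the cheapest of the seven options; ranking invariances),
  never dollar magnitudes.

## Sensitivity sweeps

`run_sweep()` varies the four management decisions — injection end year,
removal start year, removal rate, planting rate — one at a time by default
(factorially on request), re-running the scenario per grid point. One
structural coupling matters: in the inject-then-remove scenarios the
removal start is tied to the injection end (removals begin after injections
cease), so varying the injection end moves the removal start with it,
preserving the base offset. Without the coupling, "latest injection end"
could not maximize basal area, since removals would begin mid-program
regardless. Decisions a base scenario does not use cannot be varied
(validation error).

## The configuration fixture generator

`fixture_generator(seed)` emits random *valid* configurations — mortality
fractions anywhere in [0, 1], populations up to 10⁴ trees, arbitrary sorted
cost brackets, horizons of 1–40 years, randomized scenario rule-sets — for
property tests: conservation of counts, monotonicity of ash, non-decreasing
cumulative discounted cost, schema round-trips. It emulates the *shape* of
valid inputs, not realistic cities: a green property test establishes that
the accounting identities hold everywhere in the parameter space, not that
any particular trajectory is realistic. The simulator itself contains no
randomness; identical inputs are bit-for-bit reproducible, which the test
suite checks on the CLI's CSV output.

## Known limitations

* Population-level medians, not an individual-tree inventory; no spatial
  structure; a single ash and a single non-ash class.
* Condition ratings and mortality rates are held constant over the horizon;
  if injected ash decline progressively, injection scenarios are
  optimistic.
* Dollar outputs follow the printed parameters but, as noted, the source's
  own dollar tables embed unstated conventions; treat absolute cost/value
  levels as internally consistent rather than externally comparable.
* The proactive-planting scenario's non-ash counts use the package's 1:1
  cap convention, which differs from the (unreproducible) printed values.
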