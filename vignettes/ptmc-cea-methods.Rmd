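---
title: "Modelling methods: active surveillance versus early surgery for PTMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: active surveillance versus early surgery for PTMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmcCEA)
```

## The decision problem

Papillary thyroid microcarcinoma (PTMC, papillary thyroid cancer under
1 cm) is heavily overdiagnosed, and most tumours never progress. Two
management strategies compete for a low-risk patient: **active surveillance
(AS)** — semi-annual monitoring of the untreated tumour, operating only on
progression — and **early surgery (ES)** — upfront hemithyroidectomy (HT)
followed by post-operative monitoring. `ptmcCEA` compares their lifetime
discounted costs (Chinese yuan) and quality-adjusted life-years (QALYs) with
a Markov cohort state-transition model, for a reference case diagnosed at
age 40 and followed in 1-year cycles to the 80-year life expectancy (ages
20 and 60 are packaged subgroup scenarios, run over 60 and 20 cycles).

## Health states and strategy graphs

The source description names four clinical events — stable disease, disease
progression (tumour growth or new nodal disease), lateral lymph-node
metastasis, and death — and the surgery each progression event triggers,
but not the full transition graph. The packaged graphs
(`inst/extdata/strategy_as.yaml`, `strategy_es.yaml`) are the smallest
graphs consistent with that mapping in which every transition-probability
input binds to a distinct role:

* **AS**: `StableAS` → (growth → HT; nodal metastasis → total
  thyroidectomy, TT), each surgery splitting immediately into
  no-complication / permanent-complication / temporary-complication /
  operative-death outcome states; post-HT recurrence → completion TT or
  lateral lymph-node dissection (LND); post-TT recurrence → redo LND.
* **ES**: the same post-surgical subgraph, with the upfront HT applied as
  the *initial occupancy* (the HT outcome split at cycle 0, surgery charged
  undiscounted).

Choices made where the source was silent:

* **"Stable disease after HT" (0.684)** has no self-evident edge: as an
  annual stay-probability it would leak a third of the cohort each year. It
  is interpreted as the probability that a post-HT recurrence is still
  surgically confined (→ completion TT); the complement proceeds to lateral
  LND. This keeps the parameter on a single auditable edge.
* Six event-style utilities (e.g. *Active surveillance* 0.11, *Disease
  progression* 0.54) describe transient decision-tree nodes, not chronic
  states; 0.11 for asymptomatic surveillance is implausible against the
  0.99 used for AS stable disease. They load and are varied in one-way
  sensitivity analysis but bind to no state; the load log flags them.
* **Temporary complications** occupy their state for exactly one cycle and
  resolve to the no-complication state; **permanent** states persist until
  death.
* **Background mortality is off**: only the operative death probabilities
  appear in the inputs, and inventing a life table would change both arms'
  totals. The cohort therefore survives to the horizon unless operated.
* Ages at or above 80 reuse the 70–79 progression band (only reachable as
  an off-by-one guard).

## Parameters and the decade-band unit conflict

All transition probabilities and utilities live in structured parameter
files. The progression inputs are decade-banded (ages 20–29 … 70–79). The
printed band values (0.22, 0.084, 0.038, …) are approximately ten times the
annual rate the source text itself derives from a 10-year cumulative
incidence (3.7% over 10 years → 0.38%/year via `r = -log(1-p)/t`), an
internal inconsistency of the inputs. Both readings ship:

* `table1_verbatim` — band values used as annual probabilities, exactly as
  printed;
* `text_canonical` — band values treated as 10-year cumulative incidences
  and converted with the documented formula (**default**, because the model
  needs annual per-cycle probabilities and the text's own worked example
  uses this conversion).

The conflict is recorded in the parameter set's load log rather than
silently resolved. Under the verbatim reading a 40-year-old's cohort leaves
surveillance at 7.6%/year and AS accrues *fewer* QALYs than ES; under the
canonical reading AS is slightly more effective, matching the source's
qualitative conclusion.

## Rewards, discounting, numerical choices

Rewards accrue at end of cycle: the occupancy after `k` transitions is
weighted by state utilities and per-cycle costs and discounted by
`(1+r)^-k` (r = 3%, varied 1–5%). No half-cycle correction is applied — the
source never mentions one — but `half_cycle = TRUE` switches to trapezoidal
accrual. One-time surgery costs are charged to the flow entering the
operated state in that cycle, at that cycle's discount factor; self-loops
never re-charge an entry cost, and the edge resolving a temporary
complication is marked `charge_entry: false` so recovery is not billed as a
second operation. Occupancy rows are checked to sum to 1 within 1e-10 every
cycle; a residual edge per state absorbs floating-point slack, and a
residual that would be negative (draws summing above 1) aborts with the
state named.

## Synthetic costs and calibration

The study's itemised unit costs come from an unavailable supplement, so the
packaged schedule (`costs_synthetic_default.yaml`) is **synthetic**: an
itemised 2021-CNY fee schedule assembled from the described surveillance
regimen (two annual visits with ultrasound, thyroid function/blood tests
and laryngoscopy; chest CT and contrast-enhanced neck CT once a year while
the tumour is in situ), plus surgery and complication-management items,
each with a documented plausibility range. Post-resection follow-up is
modelled as a de-escalated regimen (visits, ultrasound, labs): the printed
lifetime totals — AS costlier than ES over 40 years — are only attainable
if in-situ surveillance is more intensive than post-surgical follow-up,
which matches routine de-escalation after curative resection.

`calibrate_costs()` rescales the *surgical* and *surveillance* item groups
so the reference-case lifetime totals hit the printed ¥53,461 (ES) and
¥74,198 (AS). Because discounted lifetime cost is exactly linear in unit
costs, the two factors solve a 2×2 linear system assembled from
group-masked model runs; the solution is verified by rerun and a bounded
least-squares fallback covers infeasible targets. With the packaged
defaults the factors are ≈1.18 (surgical) and ≈1.62 (surveillance), i.e.
the invented prices were of the right order. Two factors, two targets:
per-item fitting would over-fit invented detail.

## Sensitivity analyses

* **One-way DSA / tornado**: every probability and utility is pinned at its
  stated analysis range (±10% of the base value where no range is stated,
  after domain clipping), the discount rate at 1% and 5%, and every cost
  item at ±10%; both arms are rerun at each end and the ICER spread sorted.
* **PSA**: 1,000 Monte Carlo iterations; probabilities and utilities drawn
  from beta distributions parameterised by method of moments from their
  stated mean/SD, cost items from normal distributions truncated at zero by
  resampling. The stated cost uncertainty is only the ±10% one-way range,
  so the normal SD is set to `0.10/1.96` of the item value (the ±10% band
  as a 95% interval). Draws are jointly independent — no correlation
  structure is stated — and the decade-band schedules carry no stated
  uncertainty, so they stay fixed. Everything is reproducible under a
  single integer seed.

## What the packaged inputs can and cannot reproduce

The published headline totals (ES 5.2 QALYs at every horizon, AS 25.8;
ICER ¥1,009/QALY; CEAC landmarks) are internally inconsistent and depend on
the unavailable cost supplement; they are used here only as calibration
targets and documentation flags, never asserted as reproductions. The
package's own base case (canonical parameters, calibrated synthetic costs)
gives ES ≈ 22.3 and AS ≈ 22.7 discounted QALYs, ΔC = ¥20,737 by
calibration, ΔE ≈ +0.36 QALYs and an ICER ≈ ¥58,000/QALY — AS
cost-effective at the ¥242,928/QALY threshold, agreeing with the source's
conclusion at age 40 and 60 though not with its arithmetic.

Two honest divergences deserve emphasis:

* **Age 20**: the young cohort progresses fastest, so under AS a quarter of
  it eventually reaches the 0.83-utility post-TT state; incremental QALYs
  for AS are slightly *negative* (−0.25) and AS is dominated. The source
  reports AS cost-effective at all ages, but via its inconsistent totals.
* **PSA first-quadrant share ≈ 91%**, not the reported 100%. Both arms
  spend ~90% of person-time in states anchored by two utilities with
  identical printed moments (mean 0.99, SD 0.05). Method of moments gives
  the heavy-tailed Beta(2.93, 0.03), ~7% of whose draws fall below 0.95;
  drawn independently, the incremental-QALY sign flips whenever the
  AS-stable draw dips below the post-HT draw. Every negative-ΔE iteration
  in a 1,000-draw run has exactly that signature. A ≥95% share is not
  attainable under the stated moments with independent draws; the published
  100% rests on the irreproducible 20.6-QALY gap.

Passing tests therefore demonstrate internal consistency of the model and
fidelity to the stated inputs — not that the synthetic cost schedule
matches the hospital's real prices, nor that the published totals are
recoverable.

## Problem sizes

The packaged analyses are small by construction: 10–11 states, 20–60
annual cycles, 1,000 PSA iterations, a 41-input tornado; a full study run
(`run_full_study()`) completes in well under a minute on a laptop, and the
beta-moment sampling oracle in the test suite uses 10^6 draws.

## Worked example

```{r example, eval = FALSE}
model <- ce_model()                                   # canonical parameters
cal <- calibrate_costs(model$costs, model)            # hit printed totals
model$costs <- cal$schedule
run_base_case(model)$ce                               # Table-style report
psa <- run_psa(model, n_iterations = 1000, seed = 1)  # CE plane + CEAC
psa$quadrant_fractions
```
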