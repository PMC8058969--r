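---
title: "Methods: a Markov cohort cost-effectiveness model for TAS-102 regimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for TAS-102 regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem and the model

The package implements a two-arm Markov cohort comparison of TAS-102 plus
bevacizumab against TAS-102 monotherapy in chemorefractory metastatic
colorectal cancer, costed from the Japanese payer's perspective.  The
reported model has five health states: stable disease (SD), treatment
complication (TC), progression (PROG), progression with complication (PC)
and death.  Its assumptions, taken over as structural facts:

* all patients start in SD;
* death is reached only through a progression state — there is no direct
  SD-to-death transition;
* complication onset is a per-cycle probability, and the cost of managing
  a complication is incurred **once** per patient;
* complicated patients remain on treatment (no discontinuation), and
  after progression no routine-care costs accrue in either arm — only the
  one-time complication cost can arise post-progression;
* transition probabilities are constant over the 30-cycle (60-month)
  horizon of 8-week cycles.

Once-only complication accounting is enforced structurally rather than
through transition-attached one-time rewards: TC and PC are one-cycle
tunnel states whose survivors drop into post-complication twins
(`SD_postC`, `PROG_postC`) that cannot re-enter a tunnel.  The expanded
seven-state chain remains a plain Markov model, so row sums, conservation
and absorption are all mechanically checkable; `report_trace()` collapses
the twins back onto the five reported states.  The per-arm inputs are
three probabilities: progression (stable phase to PROG), death (PROG
phase to death, applied identically from PROG, PC and `PROG_postC`), and
complication onset, applied both pre-progression (SD to TC) and
post-progression (PROG to PC) with the same value, since both complication
states exist in the reported structure.

## Parameters, units, defaults

* **Transition probabilities** — per 8-week cycle, two arms x
  {progression, death, complication}; the bundled values derive from the
  published phase 1/2 and phase 2 trials of the regimens via the DEALE
  conversion (`median_to_transition_prob()`, rate `= ln 2 / median`).
  The bundled probabilities are taken as authoritative inputs; the DEALE
  operation is provided for building new scenarios, with
  `prob_rescale()` for constant-rate cycle-length changes.
* **Costs** — 2019 USD (110.05 JPY/USD), a shared ten-item table: drug
  prices per administration, administration/outpatient fees, and per-arm
  frequency-weighted complication-management costs.  Each arm selects
  items through integer per-cycle multiplicities.  A drug's price is one
  parameter even when both arms use it, so sensitivity analyses perturb
  it coherently across arms.
* **Utilities** — annual weights in [0, 1] per arm and state; the
  complication states carry their parent-state utilities (stable 0.72/0.73,
  progression 0.59 in both arms), and death 0.  One cycle at utility `u`
  contributes `u * 8/52` QALYs, which reproduces the published per-cycle
  QALY values (0.11076923, 0.11230769, 0.09076923) exactly.
* **Model constants** — 30 cycles of 8 weeks, 3.5% annual discount
  applied to costs and QALYs, willingness-to-pay $117,746/QALY (threefold
  2018 Japanese per-capita GDP; the source also prints $117,912 for the
  same threshold — the bundled scenario uses the former and records the
  discrepancy in its metadata, surfaced by `run_all()` manifests).
* **Sensitivity ranges** — every probability, cost and non-zero utility
  carries min/max at +/-25% of base (probabilities capped at 1), the
  published deterministic sensitivity design.

## Counting and discounting conventions

The source analysis does not document when state membership is counted or
how the annual rate was compounded, and these choices move totals by tens
of percent.  All are therefore explicit configuration:

* counting: `cycle_start` (cycles 0..n-1), `cycle_end` (1..n), or
  `half_cycle` (their average — the life-table correction), settable
  **separately for costs and QALYs** (`cost_counting`, `qaly_counting`).
  Up-front expenditure (drugs bought and administered at the start of each
  cycle) pairs naturally with cycle-start counting, while continuously
  accrued health outcomes pair with the half-cycle correction; this mixed
  convention is common HTA practice.
* discounting: `annualized`, `(1+r)^(-t * 8/52)` (calendar-time), or
  `per_cycle`, `(1+r)^(-t)` (each cycle one compounding period).
  Defaults are cycle-start for both quantities and annualized
  discounting.

`calibrate_conventions()` makes the reconstruction reproducible: it
enumerates the 3 x 3 x 2 convention grid crossed with a bounded integer
grid of per-cycle dose/fee multiplicities, and returns the configuration
minimising the maximum relative deviation from the published base-case
surface (per-arm costs and QALYs, incrementals), with ties broken by the
summed cost deviations and then by enumeration order — fully
deterministic.  On the bundled scenario the sweep selects cycle-start
costs with half-cycle QALYs under annualized discounting; the published
per-arm QALYs are reproducible only under half-cycle counting while the
published cost totals are reproducible (essentially exactly) only under
cycle-start counting, which is the internal tension the per-quantity
convention resolves.  The sweep report (`$report`, archived by
`scripts/acceptance.R`) shows every configuration's fit.

The bundled scenario's *default* multiplicities are a separate,
documented choice: TAS-102 twice per cycle (two 4-week courses) and
bevacizumab four times (biweekly), plus the matching administration fee
per administration.  These reproduce the published per-cycle state-cost
listing, whose figures sit on a yen-like scale about 110.5 times the
dollar values and are therefore not used as model inputs; the published
*total* costs instead imply the smaller per-cycle quantities that the
calibration sweep selects.  Both readings are kept: the defaults document
the per-cycle listing, `apply_calibration()` switches to the
total-matching configuration.

## Probabilistic sensitivity analysis

The published distribution labels ("Binomial" for probabilities and
utilities, "Gamma" for costs) are unusable as printed — a binomial needs a
size parameter.  Standard second-order practice is applied instead:

* probabilities and utilities: beta distributions, moment-matched with
  mean = base and sd = (max - min) / (2 x 1.96), so the central ~95% of
  the mass spans the +/-25% band while respecting the [0, 1] support;
* costs: gamma distributions with the same moment matching on
  [0, infinity);
* degenerate ranges (min = max) give point masses, as does a zero-base
  gamma item (with a warning).

All 20 parameters (6 transition probabilities, 10 cost items, 4 non-zero
utilities, with complication-state utilities tied to their parents) are
sampled independently per draw — the source states no correlation
structure.  A sampled draw can make a transition row infeasible
(probabilities summing above 1); such rows are renormalised — self-loop
set to zero, exits rescaled proportionally — and the event count is
logged in the result and the run manifest, rather than silently clipping
(which biases the marginals) or rejecting (which changes them).  The PSA
seed is explicit configuration (default 20210420) and every result is
bit-reproducible given the seed.

The acceptance computations show the limits of reproduction here: with
independent +/-25% sampling, roughly 2% of draws give the monotherapy arm
the better QALY outcome (the arms' survival parameters overlap), so the
northeast-quadrant fraction of the cost-effectiveness plane computes to
about 97-98% rather than the published "all re-samplings", and the CEAC
probability for the combination at $20,000/QALY computes to about 0.4
rather than the published "approximately 50%" — consistent with the
calibrated base-case ICER (~$21.8k) lying above that threshold.  These
curves are reported as produced; no attempt is made to force agreement
with the published sensitivity narrative, which is itself in tension with
the published ICER.

## Deterministic sensitivity analysis

`dsa_tornado()` re-runs the full base case twice per parameter (at min
and at max, everything else at base) and sorts by the induced ICER range.
Structural constants (cycle length, horizon, discount) and the zero death
utility are not varied, matching the published design.  An extreme that
violates row feasibility marks the entry infeasible instead of clipping;
an extreme that flips the comparison into dominance leaves an undefined
ICER (NA width) rather than a fabricated number.

## Synthetic scenarios and what the tests show

`random_scenario()` generates structurally identical two-arm scenarios —
three probabilities per arm drawn with a feasibility margin so every
+/-25% extreme still builds, progression utility below stable utility
(the clinically meaningful ordering the analysis assumes), shared cost
table with integer multiplicities — for property-based testing: mass
conservation, death monotonicity, pipeline totality over 100+ seeds.
`degenerate_scenarios()` adds named edge fixtures (zero discount,
immortal, instant progression, no complication, equal arms) with
closed-form expectations.  The generator emulates the *parameter tables*
that are this analysis's only inputs; it does not simulate patient-level
survival or trial data, so passing tests say nothing about how well DEALE
probabilities represent any real trial's hazard shape — only that the
downstream accounting is correct for whatever probabilities are supplied.

The independent check on that accounting is `microsim_oracle()`: patient-
level simulation through the same matrix and conventions, compared to the
cohort totals within three Monte-Carlo standard errors (the cohort value
is the exact expectation the simulation estimates).  The test suite runs
it at 50,000-100,000 patients on the bundled arms, a size chosen so the
standard errors are small enough to detect percent-level accounting
errors while keeping the suite fast.

## Numerical choices

* Row sums are validated to 1e-12, trace conservation to 1e-10.
* Ties in the CEAC's net-benefit comparison go to the reference arm.
* The ICER is reported only for the `comparable` dominance class; with
  zero incremental QALYs the cost sign decides cost-effectiveness.
* Calibration tie-breaks: worst deviation, then summed cost deviation,
  then enumeration order.
* `run_all()` output is full double precision in CSVs; printed tables
  round to three decimals.

## Known limitations

* Transition probabilities are time-constant (no semi-Markov behaviour,
  no tunnel lengths beyond one cycle, no time-varying hazards).
* Two strategies only; no efficiency frontier over more arms, no
  EVPI/EVPPI.
* Drug unit prices are taken as tabulated; doses are not recomputed from
  body size (carried as scenario metadata only).
* The published base-case surface cannot be reproduced exactly under any
  single configuration — the calibrated configuration agrees within 3.6%
  on QALYs and essentially exactly on costs, and the residual QALY gap is
  documented rather than absorbed by further tuning.
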