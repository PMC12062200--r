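---
title: "A stock-and-flow model of facility performance under payment-for-performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-and-flow model of facility performance under payment-for-performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p4psim)
```

## The problem

Payment-for-performance (P4P) programmes pay health providers and district
managers bonuses for meeting service-delivery targets. Their effects travel
through many interacting parts of a health system at once — drug supply
chains, worker motivation, community demand, supervision — so the net effect
of a design choice (how big the bonus is, how it is split, when it is paid)
is hard to reason about verbally. `p4psim` implements a monthly
stock-and-flow simulation of a typical primary-care facility under such a
programme, focused on two incentivised indicators:

* **IPT2** — the percentage of pregnant women receiving at least two doses
  of intermittent preventive treatment for malaria during antenatal care
  (ANC); a *content of care* indicator.
* **FBD** — the percentage of deliveries occurring at the facility; a
  *coverage* indicator.

The simulation runs for 54 months (January 2011 to July 2015 at one month
per step), spanning the implementation window of the Tanzanian programme the
model is patterned on, including the payment delays that occurred in
practice.

## Model structure

The model is built on a small generic engine (`sf_model()`, `sf_simulate()`)
in which a model is a declarative collection of **stocks** (accumulating
state), **flows** (rates in stock units per month), **auxiliaries** (derived
quantities evaluated each month in dependency order), **constants**, and
discrete **states** (counters and indices updated by assignment, e.g. trust).
Integration is explicit Euler with `dt = 1` month — the reporting unit of
the programme — with no sub-stepping; at this granularity the scheme matches
how graphical system-dynamics tools step such models. Within a month the
evaluation order is: constants, auxiliaries (topological order), flows,
stock updates, state updates.

Physical stocks (people, drugs, money) cannot go negative: realized
outflows are capped at what the stock plus the month's inflows can supply,
and the capping propagates (a capped outflow shrinks the inflow of the
stock it feeds) until a fixed point is reached. Dimensionless indices
(motivation, trust, awareness, knowledge, quality, supervision) live in
[0, 1]; "soft" stocks are additionally capped at 1. `check_units()` verifies
dimensional consistency: every flow must carry its stock's unit per month.

Six sectors are assembled by `build_p4p_model()`:

1. **Population** — a six-cohort ageing chain (neonates, infants,
   pre-schoolers, children, reproductive-age adults, adults over 50) with
   per-cohort mortality, maturation by residence time, and a fertility rate
   on the reproductive-age cohort. Its only coupling to the rest of the
   model is the monthly number of newly pregnant women.
2. **Demand and services** — each month's pregnancy cohort moves through up
   to four ANC visits; at each visit a woman drops out, is treated (one IPT
   dose, capped at two per pregnancy), or attends untreated. Treatment
   probability equals provider readiness. FBD is a weighted, clamped linear
   combination of mean ANC visits (mapped 0–4 onto [0, 1]), a distance
   index, community awareness, and perceived quality (the mean of drug
   availability and health-worker motivation, the latter standing in for
   patient-provider interaction).
3. **Facility commodities** — IPT and labour drugs are ordered quarterly
   from the Medical Stores Department (MSD), sized to expected demand; the
   MSD fulfils 75 % of the request by default. When the month's dispensable
   stock falls below half a month of expected demand, the facility buys up
   to one month of cover from facility-held funds. Availability indices are
   stock relative to one month of expected demand, capped at 1.
4. **Facility operations** — provider readiness for IPT is
   min(availability, mean(knowledge, staffing, availability, motivation)),
   so readiness never exceeds the medicine on the shelf. Motivation is the
   mean of overall drug availability, supervision quality and staffing;
   under P4P, trust in the programme joins as an equal fourth term. Trust
   rises by a saturating increment when a payment is made, is unchanged
   under short delays, and decays once a payment is four or more months
   overdue. Outreach (mean of staffing and a funds index) and first-visit
   ANC attendance feed a community-awareness stock with linear decay.
5. **Facility funding** — a funds ledger: a small routine inflow, the
   operations share of P4P payments, and emergency drug spending.
6. **District manager operations** — quarterly supervision visits whose
   quality is the mean of district resources, manager motivation and
   manager skill. Visits raise health-worker IPT knowledge by a saturating
   gain; where baseline knowledge is below 0.5 the gain only starts from
   the third visit. District managers earn their own incentive when a
   cycle has at most one stockout month and mean indicator performance of
   at least 0.6; their motivation follows the same increment/decay rule as
   facility trust.

### The intervention layer

Performance is measured over six-month cycles as the mean of the monthly
indicator values. A target is achieved if the cycle average is at least the
pre-programme baseline plus 5 percentage points, **or** at least an
absolute threshold (85 % for FBD; 80 % for IPT2, a configurable stand-in
since only the FBD threshold is published). The relative branch compares
against a *fixed* pre-programme baseline: targets in the programme were set
at commencement from pre-programme reporting data, and the observed
knock-on behaviour (a level reduction in FBD causing both early cycles'
targets to be missed) is only possible under a fixed reference — a
cycle-over-cycle ratchet is insensitive to level shifts. Once an indicator
sits above its absolute threshold, maintaining that average keeps the
target achieved.

Earned amounts accrue in a liability stock and pay out in full on the next
calendar payment month (no forfeiture). Two calendars are modelled:
`on_time` pays three months after each cycle closes (months 9, 15, 21, …)
and `actual_delayed` pays in the months observed during implementation
(13, 18, 22, 27, 34, 42) — under which the cycles closing at months 42 and
48 are never paid within the horizon, producing the severe-delay regime in
the final year. Payments are split between staff incentives (default 75 %),
which drive trust and hence motivation, and facility operations (25 %),
which replenish the funds used for emergency drug purchases.

## Parameters

All parameters live in one nested configuration (`default_config()`,
overridable from YAML/JSON via `load_config()`). The choices worth knowing
about:

* **Study-condition constants** (from the programme): horizon 54 months;
  cycle length 6; payment lag 3; delayed calendar 13/18/22/27/34/42; severe
  delay threshold 4 months; staff share 0.75; FBD absolute target 85 %; MSD
  fulfilment 0.75; quarterly ordering; ±10 % sensitivity perturbation and
  the 5/15/25 classification scale.
* **Calibrated defaults** (the published inputs are not reproduced in
  public sources, so these were chosen once to yield a plausible "typical
  facility" whose behaviour matches the qualitative findings): a synthetic
  catchment of ~10,000 persons with fertility 0.009/month (≈41 pregnancies
  a month); ANC dropout rates (0.03, 0.08, 0.15, 0.25) giving ≈3.2 mean
  visits; FBD weights (0.3, 0.2, 0.3, 0.2) with the smallest pair weight on
  perceived quality, reflecting the published note that calibration reduced
  that weight; distance index 0.9; awareness starting at 0.40 with inflow
  0.05·outreach + 0.06·ANC1 and decay 0.08/month; trust starting at 0.6
  with increment 0.05 and decay 0.10 per severely-delayed month; knowledge
  starting at 0.5 with supervision gain 0.2 and 0.5 %/month decay; staffing
  0.8 held constant (staffing is unaffected by P4P); baseline facility
  funds inflow of 5 currency units/month (alternative funding is
  deliberately limited); payment of 250 currency units per achieved
  indicator (one currency unit buys one drug dose). The payment size was
  set so that the operations share under the original 75:25 design roughly
  covers the structural MSD shortfall — the regime in which the share
  design matters, which is the point of the share experiments.
* **Pre-programme baselines** (`p4p$baseline_ipt2 = 72`,
  `p4p$baseline_fbd = 69`): the reference levels for the relative targets,
  set a few points below the model's first-cycle averages so that the
  default facility achieves its early targets with a thin margin — thin
  enough that a modest reduction in awareness or distance tips the early
  FBD cycles into missing, reproducing the cross-indicator dependency.

## What the synthetic evaluation data emulate

`generate_evaluation_dataset()` mimics the *structure* of the programme's
impact evaluation: two arms (the model with P4P on and off), three survey
waves (baseline = month 13, January 2012; short term = month 26, February
2013; long term = month 50, early 2015), and the two indicators. Each cell
is the model's mean over the 12 months preceding the wave (the surveys
sampled women who had delivered in the previous year), plus Gaussian noise
with standard deviation `noise_sd / sqrt(n_facilities)` percentage points,
truncated to [0, 100]. Defaults: 75 facilities per arm, 2 pp noise.

It does **not** emulate: facility-level heterogeneity (clustering is
collapsed into the √n scaling), survey non-response, secular trends other
than those the model itself generates, or any real Pwani data. Passing
calibration and recovery tests therefore demonstrates that the machinery
can identify parameters from data of this shape — not that the shipped
defaults reproduce the historical fit.

`calibrate()` minimises the sum of squared differences over the twelve
cells by bounded cyclic coordinate descent with successive grid refinement
(default 7 points per pass, 3 rounds) — derivative-free, deterministic, and
robust to the kinks that target thresholds and purchase triggers induce.
The default free parameters are the published "uncertain" quantities: the
perceived-quality FBD weight, the trust increment, and MSD fulfilment. The
trust increment is only weakly identified (payment events are binary, so
its imprint on twelve smoothed cells is small); quality weight and
fulfilment recover well, which is why recovery is summarised by the median.

## Numerical choices and degenerate inputs

* Conservation is exact to floating tolerance: every stock equals its
  initial value plus cumulated realized inflows minus outflows (checked to
  1e-9 over the full scenario grid).
* When demanded IPT doses exceed the dispensable stock, the model solves
  (by bisection) for the effective readiness at which demand equals stock,
  so the reported IPT2 and the drugs consumed stay mutually consistent —
  one drug unit per treatment event, exactly.
* Demand expectations used for ordering smooth provider readiness over the
  previous three months, so a single stockout month does not collapse the
  next quarterly order.
* Availability counts the month's deliveries and purchases as dispensable
  in that month (order lead time is zero: order and delivery share the
  order month, keeping the quarterly cadence visible at monthly
  resolution).
* An empty pregnancy cohort makes IPT2 return 0 with a warning; zero
  expected demand makes availability 1 (no need unmet).
* A horizon below 9 months has no payment months at all; the intervention
  layer is then inert by construction.
* The engine rejects cyclic auxiliary dependencies and non-finite values
  (naming the variable and month); unknown variable references surface as
  configuration errors.

## Design choices where the design was open

* **Evaluation order within a step** and Euler integration are the standard
  discrete system-dynamics semantics.
* **Outflow capping** (dispensing stops at stockout) rather than negative
  stocks, matching the worked replenishment example's narrative.
* **FBD functional form**: determinants are published but the form is not;
  a weighted linear combination with clamping is the simplest monotone
  choice, and every weight is exposed for calibration.
* **Trust enters motivation with equal weight** — the alternative (its own
  weight) is expressible via configuration but was not needed.
* **Emergency purchasing policy** (trigger at 0.5 months of cover, buy to
  1 month) reproduces the published artefact that the 25:75 design can
  intermittently supersede the 10:90 design through the ordering
  threshold.
* **District payment criteria** (≤1 stockout month per cycle, mean
  performance ≥0.6) are unpublished; values were chosen to make district
  payments attainable but not automatic.
* **Supervision cadence** is quarterly; quality modulates the effect size
  of a visit rather than its occurrence.
* **"Change in outcome"** in the sensitivity analysis is the maximum over
  the horizon of the absolute relative monthly change (conservative; the
  mean and endpoint variants are options). Because the model's quarterly
  stockout sawtooth can make single months swing hard, the max metric
  classifies supply-side perturbations more severely than a smoothed
  metric would.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full 54-month model; the
scenario grid is 11 distinct deterministic runs; sensitivity checks
perturb one parameter at a time in both directions. Parameter-recovery
checks use one free parameter on noiseless data (four refinement rounds)
and three free parameters at 2 pp noise across ten seeds; the noise
monotonicity property is checked at the endpoints of the noise range with
three seeds and one free parameter. These sizes were chosen so the whole
battery stays comfortably within a desktop coffee break while still
exercising every mechanism.

## Known limitations

* The model is a single "typical" facility; facility heterogeneity and the
  demand-side dynamics of delivery care-seeking (peer networks, community
  health workers, insurance funds) are out of scope, as in the source
  model, which defers them to an agent-based companion.
* Published survey inputs and calibrated weights are not public; the
  defaults here are a self-consistent synthetic calibration, and headline
  *trajectories* should not be read as reproductions of the historical
  ones. The structural constants, mechanisms, and qualitative orderings
  are the reproduction surface.
* The model is deterministic; uncertainty enters only through the
  synthetic-evaluation observation noise. No morbidity or mortality
  outcomes are modelled.

## A worked run

```{r example}
cfg <- default_config()
intervention <- run_p4p(cfg)
cfg$p4p$enabled <- FALSE
control <- run_p4p(cfg)
round(c(
  ipt2_p4p = mean(trajectory_value(intervention, "ipt2_pct")),
  ipt2_control = mean(trajectory_value(control, "ipt2_pct")),
  fbd_p4p = mean(trajectory_value(intervention, "fbd_pct")),
  fbd_control = mean(trajectory_value(control, "fbd_pct"))
), 1)
```

The horizon-average IPT2 gap between arms is large while the FBD gap is
modest — the content-of-care indicator is the one bound to the drug supply
chain that P4P operations funding relieves, whereas facility-based
delivery is buffered by its demand-side determinants.
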