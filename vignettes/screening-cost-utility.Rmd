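---
title: "Methods: a Markov cohort model for blood-pressure screening cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for blood-pressure screening cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htcue)
```

## The decision problem

A cohort of adults aged 35 with no hypertension (HT) diagnosis and no
cardiovascular disease (CVD) history is screened annually under one of four
protocols: clinic measurement alone (CBPM, the comparator), home measurement
alone (HBPM), clinic measurement with home confirmation of positives
(Serial1), or clinic measurement with home retesting of negatives (Serial2).
Protocols differ in two ways only: the sensitivity/specificity of the
combined test, and the per-person screening cost. Everything downstream —
who gets treated, who carries undiagnosed HT at elevated CVD risk, who is
treated needlessly after a false positive — follows from those two levers.

## Model structure

The cohort model has nine health states. Seven are recorded per annual
cycle: *no HT*, *undiagnosed HT* (masked hypertension, MHT), *white-coat HT
transient* (WCHT — false positives under treatment), *HT controlled*,
*HT uncontrolled*, *CVD*, and *death*. Two further states — *new HT
diagnosis* and *WCHT temporary* — are within-cycle tunnels: entrants resolve
to *HT uncontrolled* and *WCHT transient* respectively before occupancy is
recorded.

Each cycle applies, in order:

1. **HT incidence**: an age-banded annual probability moves part of the
   no-HT pool to latent (true, undiagnosed) HT.
2. **Screening** of the no-HT pool (incident cases included) and the
   previously missed MHT pool. The screened pool with true-HT fraction
   $\pi$ splits into $\pi \cdot Se$ new diagnoses, $\pi(1-Se)$ MHT,
   $(1-\pi)(1-Sp)$ new WCHT and $(1-\pi)Sp$ true negatives. Persons already
   diagnosed (WCHT, controlled/uncontrolled HT, CVD) are not re-screened;
   the no-HT and MHT pools are screened every cycle, reflecting an annual
   community campaign.
3. **Control switching** between controlled and uncontrolled HT; WCHT
   persons develop true HT at the general incidence rate and continue under
   treatment as controlled.
4. **First CVD events** from undiagnosed, uncontrolled and controlled HT;
   MHT carries the uncontrolled-HT risk (untreated disease).
5. **Mortality**: CVD case fatality (0.00699/yr below age 45, 0.0853/yr at
   45 and older — the boundary age belongs to the older stratum), then
   background non-CVD mortality for every alive state.

The cycle ordering is a modelling choice the source narrative does not fix;
this order lets screening detect both prevalent and incident cases and
resolves tunnels within the cycle. Competing risks within a cycle are
applied sequentially (CVD event, then CVD death, then background death),
each probability conditional on surviving the previous step, so occupancy
can never go negative. No half-cycle correction is applied; with annual
cycles over a lifetime horizon the correction is small relative to the
parameter uncertainty the PSA propagates, and omitting it keeps every cycle
an exact probability statement.

### Serial test composition

Assuming clinic and home test errors are conditionally independent given
true status — the only assumption under which a serial protocol's
performance is a function of the component sensitivities and specificities —

* Serial1 (confirm positives): $Se = Se_C Se_H$,
  $Sp = Sp_C + (1-Sp_C)Sp_H$;
* Serial2 (retest negatives): $Se = Se_C + (1-Se_C)Se_H$,
  $Sp = Sp_C Sp_H$.

Serial1 therefore never exceeds either component's sensitivity and never
falls below either specificity; Serial2 is the mirror image. The test suite
checks both against a brute-force enumeration of the four joint test
outcomes. Serial screening cost is the clinic cost plus the home cost for
the routed subgroup — first-stage positives ($\pi Se_C + (1-\pi)(1-Sp_C)$ of
the pool) under Serial1, first-stage negatives under Serial2 — re-evaluated
each cycle at the pool's current true-HT fraction, since that fraction
drifts as the cohort ages.

## Economic valuation

Costs accrue per cycle in three categories, each discounted by
$1/(1+r)^t$ with $r = 0.03$/yr and cycle 0 (age 35) undiscounted:

* **Screening**: screened mass × expected per-person cost.
* **Direct medical**: WCHT and controlled HT at the controlled-HT annual
  treatment cost (false positives are managed as genuine cases — that is
  exactly their economic harm); uncontrolled HT at its own cost; the acute
  CVD cost attaches once to the incident-event flow, the chronic CVD cost to
  prevalent CVD occupancy thereafter; undiagnosed HT is untreated and
  accrues nothing.
* **Direct non-medical** (transport, food, caregiver time): 4 visits/yr for
  controlled HT and WCHT, 8 for uncontrolled HT and chronic CVD, at a unit
  cost per visit; 9.83 admission days per acute CVD event at a unit cost per
  inpatient day.

Utility weights: healthy and WCHT 1, any true-HT state 0.95, CVD
$0.55 \times 0.64 + 0.75 \times 0.36 = 0.62$ (stroke and coronary disease
weighted by their shares of CVD cases), death 0. Life years are the
discounted alive mass. QALYs ≤ LYs holds by construction since all weights
are ≤ 1.

Strategies are compared by incremental cost-effectiveness ratios with
explicit dominance quadrants: a negative ICER from higher cost and fewer
QALYs marks a dominated strategy, while a positive ICER from *lower* cost
and fewer QALYs (southwest quadrant) reads as cost saved per QALY lost and
is judged against willingness to pay via net monetary benefit,
$NMB = WTP \cdot QALY - cost$, at the default threshold of 160,000
baht/QALY. A zero QALY increment leaves the ICER undefined rather than
dividing. Report tables round costs and ICERs to whole baht and LYs/QALYs to
4 decimals; all internal arithmetic is full precision.

## Parameters

The parameter file is a scalar config (`key: value`) plus one CSV table with
columns `parameter, age_lower, age_upper, value, dist_family, dist_se,
owsa_low, owsa_high, provenance`. Age-banded inputs (HT incidence, CVD event
risks, background mortality) use decadal bands 35–39, 40–49, …, 80+,
matching how the influential inputs are usually reported. Loading validates
every invariant (probabilities and utilities in [0,1], costs ≥ 0, disease
mixes summing to 1, bands contiguous and covering the horizon) and reports
*all* violations, not just the first.

The generator `default_parameter_set()` embeds the values printed in the
source study body verbatim (utilities 1/0.95/0.55/0.75/0, CVD case fatality
0.00699 and 0.0853 with the age-45 cutoff, stroke/CAD mix 0.64/0.36,
discount 3%/yr, 4 and 8 visits/yr, 9.83 acute admission days, WTP 160,000
baht/QALY, entry age 35) and fills the unprinted remainder with documented
stand-ins at field-typical magnitudes: test performance near meta-analytic
values for clinic/home measurement against an ambulatory reference
(CBPM 0.74/0.79, HBPM 0.71/0.82), HT incidence rising from 1.5%/yr at 35–39
to 5%/yr at 70+, first-CVD-event risk 0.4–6%/yr by age and control status
(controlled at half the uncontrolled risk), background mortality at
life-table magnitudes, control switching 0.20/0.35 per year (about one third
controlled at steady state), and unit costs in baht (30/120 per screen,
2,500/4,000 per treated year, 60,000/15,000 acute/chronic CVD, 300 per
visit, 500 per inpatient day). The emitted file's `provenance` column keeps
"paper" and "stand-in" values distinguishable. The default fill policy is
the central value; a seeded `"jitter"` policy (±20% uniform) exists for
robustness exercises, never for reported results. The horizon cap is age 100
— the conventional lifetime-horizon truncation — giving 65 annual cycles.

**What passing tests show, and what they do not.** The synthetic set
reproduces the *structure* of the original input table, not its calibrated
values, which are not published at usable precision. Tests and analyses on
the synthetic set therefore validate the machinery (conservation,
composition, accrual, comparison, calibration, PSA) and the qualitative
decision structure, but absolute lifetime totals are illustrative, not a
reproduction of the published Table values. The published *derived*
arithmetic — increments, ICERs, the weighted CVD utility, the NMB decision —
is reproduced exactly from the published operands.

## Calibration

Age-banded HT incidence (optionally background mortality) is adjusted by
band-specific multiplicative scalars so modeled prevalence — true HT
(undiagnosed + controlled + uncontrolled) among the alive, averaged over
each band's cycles — matches external targets. Because prevalence at a
target band responds only to incidence at equal or younger ages, the system
is triangular: the solver sweeps incidence bands in ascending age order and
root-solves each band's own prevalence residual (monotone in its scalar) by
bounded 1-D search, clipping at the bounds when a target is unreachable and
logging any clipping. Sweeps repeat until the root-mean-square residual
falls below `tol` (default 1e-4) or `max_iter`; a sweep is accepted only if
it reduces the objective, so the fit is monotone. On synthetic-truth
fixtures (`make_calibration_fixture()`) known perturbations are recovered to
well under 0.1% — far inside the 5% recovery bar the test suite enforces —
in one or two sweeps. When mortality adjustment is enabled its coordinates
are fitted by SSE minimisation over their overlapping targets, since
mortality breaks the pure triangular structure.

## Uncertainty analysis

**One-way (tornado).** Every parameter with an `owsa_low/owsa_high` range is
set to each bound with all else at base and the full model rerun; the output
is sorted by ICER swing. Default ranges are ±25% of base (clipped to valid
probability ranges) — the source does not print its ranges, so tornado
*orderings* under defaults are indicative. All bounds are validated before
any model run.

**Probabilistic (PSA).** Per replication, every non-fixed parameter is
redrawn — beta for probabilities and utilities, gamma for costs, the
standard health-economics families, converted from (mean, SE) by method of
moments with explicit feasibility checks (beta requires variance
< mean(1−mean)) — and all four strategies are evaluated on the *same* draw
(common random parameters), so per-replication rankings are internally
consistent. Default SEs are 10% of the mean for probabilities and 20% for
costs; the disease-mix fractions stay fixed so their sum-to-one invariant
holds. Draws are deterministic given (seed, replication) and leave the
caller's RNG state untouched. The default 1000 replications complete in
about half a minute on one core at the 65-cycle model size.

**CEAC.** At each willingness-to-pay value on the default grid (0–500,000
baht in 10,000 steps, always containing 160,000) a strategy's probability of
being cost-effective is the fraction of replications in which it attains the
maximum NMB; exact ties split the mass equally, so the probabilities sum to
one by construction.

## Degenerate inputs and numerical edges

* A state vector that fails conservation (sum ≠ 1 or negative entries) is
  rejected naming the offending age.
* A prevalence band with no alive mass yields `NA` with a warning, never a
  silent zero.
* `π = 0` or `π = 1` screening pools, zero-incidence and full-mortality
  parameter sets are exact special cases covered by tests.
* Beta draws with SE too large for the mean, and overrides or one-way bounds
  that violate any invariant, fail fast naming the parameter.
* Conservation is enforced to 1e-12 per cycle; determinism is exact (two
  runs are bit-identical).

## Known limitations

* Full screening adherence is assumed; real home-measurement adherence is
  partial, so screening benefits are upper bounds.
* WCHT here means any false-positive diagnosis (from clinic *or* home
  measurement), a broader definition than clinic-only white-coat effect.
* Hemorrhagic and ischemic stroke are not separate states; the disease mix
  enters only through the weighted CVD fatality, utility and cost.
* No indirect (productivity) costs; caregiver income loss is counted as
  direct non-medical cost.
* Undiagnosed HT persons who suffer a CVD event enter the CVD state and are
  thereby managed as patients; the model does not track a separate
  undiagnosed-CVD pathway.
* The stand-in inputs make absolute totals illustrative (see above); any
  substantive application should replace them with locally calibrated
  values via the parameter file.
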