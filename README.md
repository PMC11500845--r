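# htcue

Cost-utility analysis of population blood-pressure screening strategies with
a nine-state annual-cycle Markov cohort model.

## The problem

National hypertension (HT) screening programmes must choose a measurement
protocol. Clinic blood-pressure measurement (CBPM) is cheap but error-prone:
its false positives create *white-coat hypertension* (WCHT — people treated
for HT they do not have) and its false negatives create *masked hypertension*
(MHT — true HT left undiagnosed and untreated, at elevated cardiovascular
risk). Home measurement (HBPM) and two serial protocols change that error
trade-off at different screening cost:

* **CBPM** — clinic measurement alone (the comparator / current practice),
* **HBPM** — home measurement alone,
* **Serial1** — CBPM, then HBPM confirmation for clinic *positives*
  (fewer false positives),
* **Serial2** — CBPM, then HBPM retesting for clinic *negatives*
  (fewer false negatives).

`htcue` is written for health-economic modellers evaluating such screening
policies. It follows a screened cohort from age 35 over a lifetime horizon
through the states *no HT, undiagnosed HT, white-coat HT (transient),
HT controlled, HT uncontrolled, CVD, death* (two further tunnel states —
new diagnosis and temporary WCHT — resolve within a cycle), and accrues
discounted costs and quality-adjusted life years (QALYs) from a societal
perspective.

## The model in brief

Serial test performance follows from the component sensitivities and
specificities under conditional independence:

* Serial1: `Se = Se_C · Se_H`, `Sp = Sp_C + (1 − Sp_C) · Sp_H`
* Serial2: `Se = Se_C + (1 − Se_C) · Se_H`, `Sp = Sp_C · Sp_H`

A screened pool with true-HT fraction π splits into
`π·Se` new diagnoses, `π·(1−Se)` masked HT, `(1−π)·(1−Sp)` white-coat
diagnoses and `(1−π)·Sp` true negatives. Each annual cycle applies HT
incidence, screening, control-status switching, first CVD events
(masked HT at uncontrolled-HT risk) and mortality (CVD case fatality
0.00699/yr under age 45, 0.0853/yr at 45+, then background mortality).
Costs (screening, direct medical, direct non-medical), life years and QALYs
(utilities: healthy/WCHT 1, HT 0.95, CVD = 0.55·0.64 + 0.75·0.36 = 0.62,
death 0) are discounted at 3%/yr. Strategies are compared by incremental
cost-effectiveness ratio `ICER = ΔC/ΔE`, dominance quadrant and net monetary
benefit `NMB = WTP·QALY − cost` at the Thai threshold WTP = 160,000
baht/QALY. The package also calibrates age-banded incidence to prevalence
targets, and quantifies uncertainty by one-way (tornado) and probabilistic
sensitivity analysis (PSA) with cost-effectiveness acceptability curves
(CEACs).

The full calibrated input table of the original study is not published at
usable precision, so `default_parameter_set()` embeds every value printed in
the study body verbatim and fills the rest with documented stand-ins (the
emitted parameter file's `provenance` column separates the two). Absolute
lifetime totals under the stand-ins are therefore illustrative; the
comparison arithmetic, model mechanics and uncertainty machinery are exact.

## Worked example

```r
library(htcue)
ps <- default_parameter_set(synthetic_spec(seed = 1))
bc <- base_case_analysis(ps, comparator = "CBPM")
print(bc$icer, digits = 4)
```

```
       comparison delta_cost  delta_ly delta_qaly icer_ly icer_qaly  dominance_class
1    HBPM vs CBPM      -1531 -0.000776 -0.0007778 1973583   1969011     trade_off_SW
2 Serial1 vs CBPM     -25925 -0.011911 -0.0097766 2176604   2651782     trade_off_SW
3 Serial2 vs CBPM       5598  0.002050  0.0022108 2730609   2532004     trade_off_NE
```

Under the stand-in inputs Serial1 saves 25,925 baht per person over a
lifetime while losing 0.0098 QALYs (a southwest-quadrant trade-off: its
positive "ICER" of 2,651,782 reads as baht *saved* per QALY *lost*, far above
the 160,000 threshold, so the saving outweighs the loss); Serial2 buys a
marginal 0.0022 QALYs at the highest cost. At WTP 160,000 baht/QALY the
maximum-NMB strategy is Serial1, and a 1000-replication PSA gives it a 100%
probability of being cost-effective — the same decision structure the
published analysis reports:

```r
psa <- run_psa(ps, replications = 1000, rng_seed = 1)
ceac(psa)[17, ]   # WTP = 160,000
#      wtp CBPM HBPM Serial1 Serial2
#   160000    0    0       1       0
```

The numbered drivers under `analysis/` run the full workflow and write
plot-ready tables under `results/`: `01_base_case.R` (parameter file, cohort
traces, publication-style results table), `02_calibration.R` (parameter
recovery: a known 1.3× incidence perturbation at ages 40–49 is recovered to
within 0.0001%), `03_owsa.R` (tornado tables per comparison) and
`04_psa.R` (PSA samples, CE-plane points, CEACs).

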