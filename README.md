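# hfscreen

A Markov cohort cost-effectiveness model of screening for unrecognized
heart failure (HF) in community-dwelling patients with type 2 diabetes
aged 60 or over. Roughly a quarter of such patients have HF — mostly with
preserved ejection fraction (HFpEF) — that their GP does not know about.
Detecting it earlier changes treatment, utilities and costs. This package
asks the health-economic question: which screening strategy, if any, buys
quality-adjusted life-years (QALYs) at an acceptable price?

The package is aimed at health-economic modellers: every layer (inputs,
cohort engine, screening events, discounted accrual, incremental
analysis, probabilistic sensitivity analysis, scenario grids) is an
exported, tested function, so the model can be re-parameterized,
extended, or used as a worked example of a decision-analytic cohort
model in R.

## The model

A cohort starts at age 60 in one of eleven states: *diabetes without
diagnosed HF*; NYHA classes I–IV, each split into *undetected* and
*detected*; and two absorbing states, *death from HF* and *death from
other causes*. Cycles are 3 months (the regular diabetes consultation
interval) over a lifetime horizon. Within a cycle, events compose in the
order death → incident HF → NYHA movement:

- HF death: annual probabilities by NYHA class and detection status,
  converted to the cycle scale by the constant-hazard map
  `p_cycle = 1 − (1 − p_annual)^0.25`;
- other-cause death: a Gompertz life table anchored at the published
  age-60 mortality (0.010 men, 0.007 women);
- incident HF (658/666 per 100,000 person-years, men/women) enters at
  NYHA II undetected;
- NYHA movement: the third power of a 1-month NYHA transition matrix,
  applied within each detection stratum conditional on survival.

Six strategies are compared: no screening (0); once-in-a-life screens of
increasing intensity built on electronic-medical-record and symptom
checks (1), adding physical examination (2), NT-proBNP (3), ECG (4); and
direct echocardiography for everyone (5). Screening moves undetected
mass to detected states according to NYHA-specific sensitivities;
echocardiography is a perfect arbiter, so false positives cost an echo
but produce no false diagnoses. Strategies 1–5 re-screen annually with
the EMR/symptoms profile.

Detected states carry higher utilities (except NYHA IV), slightly lower
mortality, and detection-specific costs. QALYs are discounted at 1.5%
per year and costs at 4% (Dutch guidelines). Strategies are compared by
incremental cost-effectiveness ratios (ICERs) after removing strongly
and extendedly dominated options; parameter uncertainty is propagated by
Monte-Carlo sampling (Beta for probabilities and utilities, Gamma with
variance equal to the mean for costs, Dirichlet for the baseline
prevalence block) into cost-effectiveness acceptability curves (CEACs).

Two published inputs were never printed: the 1-month NYHA matrix and the
life table. Seeded generators (`generate_nyha_matrix()`,
`generate_life_table()`) supply them, with generator intensities
calibrated once (`calibrate_nyha_matrix()`) so that no-screening and
EMR/symptoms life expectancy match the published totals.

## Worked example

```r
library(hfscreen)
bc <- run_base_case("men")
print(bc)
```

```
Base-case analysis (men)

 strategy                                   name life_years  qalys total_cost
        0                           No screening     14.716 10.682       9053
        1                           EMR/symptoms     14.762 10.831       9710
        2              EMR/symptoms/PhysicalExam     14.762 10.831       9718
        3     EMR/symptoms/PhysicalExam/NTproBNP     14.762 10.831       9736
        4 EMR/symptoms/PhysicalExam/NTproBNP/ECG     14.762 10.831       9758
        5                       Echocardiography     14.763 10.835       9770

Incremental cost-effectiveness analysis
 strategy effect cost            dominance        icer
        0 10.682 9053         nondominated (reference)
        1 10.831 9710         nondominated       4,407
        2 10.831 9718 extendedly_dominated   dominated
        4 10.831 9758   strongly_dominated   dominated
        3 10.831 9736 extendedly_dominated   dominated
        5 10.835 9770         nondominated      16,263
```

Reading this: screening gains about 0.046 life-years and 0.15
discounted QALYs per man at ~€660 extra lifetime cost. The middle
strategies (2–4) add cost without meaningful extra effect and drop out
as dominated; the frontier runs no screening → EMR/symptoms →
echocardiography, with EMR/symptoms costing ~€4,400 per QALY gained —
well under the conventional €20,000/QALY willingness to pay.

Uncertainty and the HFpEF treatment scenario:

```r
p <- default_parameters("men")
cloud <- run_psa(screening_strategies(), p, n = 10000, seed = 1)
plot(ceac(cloud, seq(0, 80000, by = 500)))

scenario_grid(screening_strategies(), p, rho_values = c(0, 0.5, 1))
```

```
 rho comparison delta_qalys delta_cost  icer
 0.0     1 vs 0    0.149100        657  4407
 0.0     5 vs 1    0.003715         60 16263
 0.5     1 vs 0    0.207900        835  4014
 0.5     5 vs 1    0.005222         65 12535
 1.0     1 vs 0    0.269100       1019  3786
 1.0     5 vs 1    0.006800         71 10399
```

`rho` is the effectiveness of HFpEF treatment relative to HFrEF
treatment (0 = none, the base case). If an effective HFpEF drug arrives,
every screening strategy's ICER improves.

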