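---
title: "Methods: a Markov cohort model of heart-failure screening in type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of heart-failure screening in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfscreen)
```

## The decision problem

Unrecognized heart failure (HF) is common in older patients with type 2
diabetes; most of it is HF with preserved ejection fraction (HFpEF), for
which no prognosis-modifying drug existed when the reference evaluation
was done, while the minority with reduced ejection fraction (HFrEF)
benefits from guideline treatment. Screening at the routine diabetes
consultation can move patients from *undetected* to *detected* HF, which
changes their utility, their costs, and (slightly) their mortality. The
model quantifies whether that trade is worth making, and for which of
six screening strategies.

## States and dynamics

Eleven mutually exclusive states: diabetes without diagnosed HF, NYHA
classes I--IV each split into undetected/detected, and two absorbing
death states (HF death, other-cause death). Cycles are 3 months; the
horizon is lifetime, implemented as "surviving mass below $10^{-8}$ or
age 110, whichever first".

Within a cycle, from any NYHA state, events compose in a fixed order:

1. **HF death** with per-cycle probability
   $1-(1-p_{\text{annual}})^{0.25 m}$, where $p_{\text{annual}}$ is the
   annual HF mortality for that NYHA class and detection status and $m$
   is a hazard multiplier (below; $m=1$ in the base case).
2. **Other-cause death** among HF survivors, from the life table at the
   current age.
3. **NYHA movement** conditional on surviving both, using the third
   matrix power of a 1-month NYHA transition matrix, within the current
   detection stratum.

From the no-HF state the order is other-cause death, then incident HF
(annual incidence $\times$ a diabetes multiplier, default 1), entering
NYHA II undetected — new HF presents symptomatically around class II.

The published source is silent on within-cycle ordering; ordering
differences are $O(\text{cycle}^2)$ and the chosen order (HF death takes
precedence in HF states) makes the detected NYHA III death cell equal
the cycle-converted published mortality exactly, which is convenient for
verification. Detection status never changes inside the transition
matrix: screening is an *event* applied to the state distribution at
cycle boundaries — at cycle 0 with the strategy's own test profile, and
every fourth cycle thereafter (annually, strategies 1--5 only) with the
EMR/symptoms profile.

## Treatment effect and the HFpEF scenario dial

Detected patients are treated; treatment multiplies the HF mortality
hazard by $h = 0.90$ (default) in the HFrEF share $1-f$ and by
$1-\rho(1-h)$ in the HFpEF share $f = 0.826$, giving the mix

$$m(\rho) = (1-f)\,h + f\,(1 - \rho(1-h)),$$

with $\rho \in [0,1]$ the relative effectiveness of HFpEF treatment
($\rho = 0$: none, the base case; $\rho = 1$: HFrEF-equivalent).

A design choice worth stating: the published detected-state mortalities
are *lower* than the undetected ones by roughly the factor $m(0)$, i.e.
they already embed the current treatment mix. The engine therefore
applies the multiplier **relative to its base-case value**,
$m(\rho)/m(0)$, so that $\rho = 0$ reproduces the published detected
mortalities untouched and $\rho > 0$ expresses only the *additional*
benefit of extending effectiveness to the HFpEF share.
`treated_mortality()` exposes the absolute form for standalone use. The
default $h = 0.90$ reflects the ~10% all-cause mortality relative risk
reduction that HFpEF trials have (unsuccessfully) chased and that
guideline HFrEF therapy achieves per agent; it is a configuration
scalar, not an estimate.

## Screening events

Only the no-HF state and undetected NYHA states are screened: detected
patients are under cardiology care, and the dead are dead. Per NYHA
class, a fraction equal to the strategy's sensitivity of the undetected
mass moves to the detected state. Costs per cohort member:

- GP screening cost for *every* screened person (the strategy is priced,
  not the positives);
- echocardiography (€169.38) for every referral — new detections plus
  $(1-\text{specificity})$ of the no-HF mass; under direct
  echocardiography, everyone screened;
- an ECG stress test (€94.75) per new diagnosis. False positives do not
  incur it: echocardiography (a perfect reference standard here) clears
  them first.

The annual follow-up screen re-incurs the full EMR/symptoms GP cost
(€6.39) by default; `gp_followup_cost` overrides it for settings where
the check is folded into the routine consultation.

## Baseline detection status

The published baseline prevalence table has a nonzero *detected* column,
although the cohort excluded patients with a confirmed diagnosis. By
default the model pools both columns into the undetected states
(total prevalence 0.375 over NYHA I--IV) and lets the cycle-0 screening
event perform the first detections; `baseline_detected = TRUE` starts
the printed detected column verbatim instead. The pooled start is the
one consistent with comparing *screening* strategies: under no screening
nobody is detected until clinical presentation, which this model does
not include — a known conservatism discussed under limitations.

## Economics

Utilities (EQ5D scale, shared across genders) and annual HF costs
(gender- and detection-specific) attach to states; only the *increase*
over routine diabetes care is counted, so the no-HF state costs nothing.
QALYs are discounted at 1.5% per year and costs at 4%, at cycle start
($t = \text{cycle} \times 0.25$ y); a half-cycle correction is available
(`half_cycle = TRUE`) and off by default. Both discounted and
undiscounted life-years and QALYs are reported.

One empirical observation drives a choice elsewhere: the published QALY
expectancies are numerically consistent with *undiscounted* accrual
(their ratio to life expectancy equals the occupancy-weighted mean
utility, ~0.84, whereas 1.5% discounting over a ~15-year horizon would
push the ratio near 0.75). The calibration targets (below) therefore use
undiscounted life-years and QALYs, while the cost-effectiveness analysis
itself uses the discounted quantities as stated.

An alternative *derived* cost path (`derive_hf_costs()`) reconstructs
the annual cost table from a base hospitalization/nursing cost weighted
by per-NYHA hospitalization hazard ratios, adjusted between detection
statuses by their mortality ratio, plus detected-only GP and medication
components; it exists for configuration-driven reanalysis and is not
used by the defaults, which read the published table directly.

## Incremental analysis

Strategies are sorted by effect (ties by cost); strong dominance removes
strategies that cost more for no more effect; extended dominance
iteratively removes strategies whose incremental cost-effectiveness
ratio (ICER) exceeds that of the next step until frontier ICERs increase
strictly. Exact ties in both dimensions are kept and flagged. ICERs are
kept unrounded internally; printing rounds to whole euros. The frontier
is provably the set of net-monetary-benefit optima over non-negative
willingness to pay; the test suite checks this against a convex-hull
oracle on randomized instances.

## Probabilistic sensitivity analysis

Sampling families follow the published table: Beta for test
characteristics, Beta for utilities, Gamma with variance equal to the
mean for every cost, Dirichlet for the baseline prevalence block;
incidence and mortality stay fixed. Every distribution is mean-centred
on its point estimate (verified to $10^{-9}$), so the cloud scatters
around the deterministic result.

- Sensitivities/specificities: Beta with effective true-positive /
  false-negative counts $p\,n_k$ and $(1-p)\,n_k$, where $n_k$ splits
  the cohort's implied HF cases (581 × 0.277 ≈ 161) over NYHA classes by
  the baseline prevalence mix (non-cases, 581 × 0.723, for
  specificities). Non-integer counts are deliberate: they keep the mean
  exactly at the printed value, which integer rounding would break.
  Printed 0.000/1.000 cells are degenerate and stay fixed.
- Utilities: method-of-moments Beta around the printed mean with a
  standard error of 0.02 (`utility_se`), a typical cohort-level EQ5D
  precision; only means were published.
- Dirichlet draws are rescaled to the block's base total so the no-HF
  remainder is preserved.

Parameters are sampled once per draw and shared across all six
strategies (common random parameters — required for meaningful
incremental clouds). Draws producing an invalid parameter set are
rejected and redrawn, with a count kept. The reference analysis uses
10,000 draws; the test suite uses 2,000 for the mean-centring check and
smaller clouds elsewhere, sizes chosen to make Monte-Carlo error small
relative to the assertion tolerances.

CEACs report, per willingness-to-pay value, the fraction of draws in
which each strategy attains the strictly highest net monetary benefit,
with exact ties split equally.

## Synthetic inputs and calibration

Two load-bearing inputs of the published analysis were never printed:
the 1-month NYHA transition matrix and the life table. The package
generates both:

- `generate_nyha_matrix()`: one-class worsening at a progression
  intensity, one-class improvement at an improvement intensity,
  multi-class jumps geometrically damped (factor 0.25), diagonal as
  remainder; optional seeded log-normal jitter. NYHA IV → I is possible,
  as the state diagram requires.
- `generate_life_table()`: Gompertz hazard
  $h(a) = h_{60}\,e^{r(a-60)}$, anchored so the age-60 annual
  probability equals the published 0.010 (men) / 0.007 (women).

The shipped defaults — progression 0.207/month, improvement 0.323/month,
Gompertz slope $r = 0.118$/y — were fixed **once** by minimizing the
squared deviation of no-screening and EMR/symptoms (undiscounted) life
expectancy and QALY expectancy from the published men's totals
(14.726/12.345 and 14.742/12.477); the test suite verifies the achieved
life expectancies land within 0.1 years of those targets. The
slope is steeper than a general-population table because the age-60
anchor is fixed at the printed point value while the diabetic cohort's
subsequent mortality must be reached through the slope alone. Four
scalar targets cannot identify sixteen matrix entries plus a slope: the
fit is a ridge (roughly, the progression/improvement *ratio* and the
overall pace trade off), and the shipped matrix is one well-fitting
member of the generator family, versioned with the package.
`calibrate_nyha_matrix()` re-runs the search over the two intensities
(derivative-free Nelder--Mead on the log scale, default budget 300 loss
evaluations, each two cohort runs) for any target vector; it reports the
achieved loss rather than asserting equality.

`generate_patient_table()` emulates the screening cohort at the row
level (HF status, HFpEF/HFrEF split, NYHA class, detection, utility and
cost draws whose group means converge to the published summary values).
It is an emulation of summary statistics: it carries no real
correlation structure between age, severity and utility, no repeated
measurements, and no missingness — so tests passing on it demonstrate
model arithmetic, not fidelity to individual-level patient data.

## Numerical choices

- Stopping: surviving mass $<10^{-8}$ or age 110; with the default
  inputs the cohort is numerically extinct before the cap matters.
- Transition matrices are rebuilt only when an age-indexed input
  changes (per whole year of age) and shared across strategies within a
  PSA draw.
- Age scaling of NYHA worsening (off by default) multiplies
  above-diagonal entries by the scale ratio, divides below-diagonal ones
  by it, and renormalizes with a warning if a row overflows.
- Row sums are validated to $10^{-9}$; occupancy conservation is tested
  at the same tolerance at full scale.
- QALY ties in the ranking are broken by lower cost; equal-effect,
  higher-cost strategies are strongly dominated (the published table
  prints exactly this case).

## Limitations

- No individual-level simulation: cohort expectations only, so no
  variance within a strategy beyond parameter uncertainty.
- No acute exacerbation events, end-of-life cost surcharge, or
  misclassification-driven care before death; the published analysis
  shares these omissions and argues they bias against screening.
- Screening attendance is 100%; test-retest correlation across annual
  screens is not modelled.
- The synthetic NYHA matrix and life table are calibrated stand-ins;
  absolute totals inherit their under-determination even though the
  incremental comparisons are far less sensitive to it.
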