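---
title: "Methods: the early cost-utility model behind vacomhta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the early cost-utility model behind vacomhta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacomhta)
```

## The decision problem

`vacomhta` evaluates a soft robotic sock (VACOM) that combines
intermittent pneumatic compression (IPC) with robotic ankle mobilisation
for immobilised post-stroke inpatients, against IPC plus manual ankle
movement. Prolonged immobilisation causes both deep vein thrombosis
(DVT, with pulmonary embolism as its dangerous sequela) and ankle
contracture; the sock targets both. The evaluation is *early*: it is run
before the first clinical trial, on literature-style parameter estimates,
to ask what the device could be worth, which parameters drive that value,
what price premium the evidence supports, and whether reducing parameter
uncertainty is worth further research.

## Model structure and assumptions

The model is a two-period decision tree over a 1-year horizon from a
healthcare-system perspective (2019 Singapore dollars), evaluated
separately for ischemic (`is`) and hemorrhagic (`ha`) stroke cohorts
because their baseline mortality differs.

**Inpatient period (month 1).** Chance nodes in sequence: DVT; PE given
DVT; inpatient death. Two structural choices deserve note:

* *PE is nested under DVT.* PE is modelled as a DVT sequela, so the
  parameter is `prob_pe_dvt` = P(PE | DVT) and the three inpatient states
  are no-DVT-no-PE (`ndnp`), DVT-without-PE (`dnp`) and DVT-with-PE
  (`dp`).
* *Inpatient mortality is one probability per cohort by default.* The
  table may supply per-state overrides (`prob_death_inpat_dnp`,
  `prob_death_inpat_dp`) when evidence supports state-dependent inpatient
  mortality; the cohort-level default was chosen for parsimony, since an
  early model has no reliable estimate of the interaction.

Patients who die as inpatients are assumed to die on day 15 of the stay.

**Post-discharge period (months 2–12).** Survivors face exactly one of
six mutually exclusive outcomes — well, recurrent stroke, recurrent DVT,
recurrent PE, ankle contracture, death — occurring at the start of month
7. The "well" branch is the residual `1 − Σ` of the others; a negative
residual is rejected as an invalid parameter set rather than clipped.
Whether recurrent stroke carries additional within-horizon mortality is
unmodelled (it would need a parameter no early source provides); its
utility and cost consequences are carried by the recurrent-stroke state
itself.

**Strategy effects and compliance.** The sock acts multiplicatively on
flagged baseline probabilities — DVT via `rr_dvt_vac_ipc` and ankle
contracture via `rr_ankcon_vac` by default (the mapping is configurable
via a scenario's `effects`). Compliance is binary at the patient level;
because the tree is linear in the pathway probabilities, the cohort-level
expectation equals the mixture `RR_eff = c·RR + (1 − c)`, which is how
`effective_relative_risk()` implements it. Non-compliant sock patients
still incur the price premium — the device is dispensed either way — which
is the conservative choice against the intervention. Products are clipped
at 1 (`arm_probability()`).

**QALY accrual.** Utilities are combined multiplicatively for comorbid
states: the inpatient utility is `util_inpat`, multiplied by `util_dvt`
and `util_pe` for the DVT/PE states. The multiplicative adjustment is
applied to the *inpatient* month only; post-discharge states carry their
own absolute utilities (`util_postdis_*`), on the view that the acute
events are resolved by discharge and the post-discharge state utility
already describes the health state lived in.

Time weighting uses two deliberate conventions (`timing_constants()`):

* months count as 1/12 year for QALY weights, so a full well year is
  exactly 1.0 QALY;
* the day-15 death rule uses a 30-day month: inpatient deaths accrue
  `15/365` year of inpatient utility and half of the 1-month stay cost.

Survivors accrue month 1 at the inpatient-state utility, months 2–6 at
the post-discharge well utility, and months 7–12 at the outcome utility;
post-discharge death truncates accrual (and monthly care costs) at the
start of month 7. A discount-rate field exists for interface completeness
but defaults to 0 — over a 1-year horizon discounting is a no-op.

**Whole-pathway QALY mode.** Instead of state utilities, a table may
supply one QALY value per pathway (`qaly_ndnp_1_12m_well`,
`qaly_dp_inpat_death`, ...), the granularity at which early-HTA parameter
tables are often published. `pathway_qaly()` passes such values through
unchanged, and `as_whole_pathway()` converts a decomposed table so the two
modes agree exactly (a tested round-trip). The packaged default table uses
whole-pathway mode, which also makes the tornado rank the pathway-QALY
parameters directly.

## Parameters, distributions, uncertainty

Each row of the parameter table carries a role, a base value, a PSA
distribution and a DSA range. Distribution families follow standard
health-economic convention, chosen so draws respect role bounds by
construction: **beta** for probabilities, utilities and whole-pathway
QALYs; **gamma** for costs; **lognormal** for relative risks; `fixed` for
quantities held constant. `moments_to_dist()` fits any of these from a
(mean, SE) pair by method of moments, reproducing the mean to 1e−9; an SE
infeasible for the beta family (`se² ≥ m(1−m)`) is rejected with the
bound stated.

When a row carries no uncertainty information, the default SE is **20% of
the base value** (capped below the beta feasibility bound), and the DSA
range defaults to the fitted distribution's 2.5th/97.5th percentiles —
a common early-HTA convention, overridable per row. PSA draws are sampled
column-by-column in alphabetical parameter order from one seeded stream,
making draw matrices reproducible and invariant to table row order, and
both strategies are evaluated on the same draws (common random numbers),
which reduces CEAC and EVPI variance.

Named scenarios fix the sock's ankle-contracture RR (0.3 optimistic, 0.9
conservative, per the innovator's efficacy expectations) and the price
premium (S$150 revised, S$300 original; S$1,000 appears in the
value-of-information grid). `apply_scenario()` resets the RR row's base
value and *refits* its distribution and DSA range under the 20% rule, so
the parameter remains part of PSA and DSA rather than collapsing to a
constant.

## Decision statistics

* `incremental()`: ΔC, ΔE, ICER (undefined at ΔE = 0), NMB = λ·ΔE − ΔC at
  λ = S$75,000/QALY by default. Dominance is quadrant-aware: in the
  southwest quadrant (cheaper, less effective) the NMB sign decides,
  because the ICER is sign-ambiguous there. NMB ties count against the
  intervention, so CEAC values are fractions of draws with strictly
  positive NMB.
* `premium_icer_curve()` re-evaluates the sock arm at each premium and
  asserts the affine identity (slope `1/ΔE`) rather than assuming it.
* `one_way_dsa()` reports percent change in incremental NMB, parameter at
  DSA low/high with all else at base; span ties break alphabetically so
  output is deterministic. A base NMB of exactly 0 switches to absolute
  changes, flagged in the `metric` column.
* `max_premium()` uses the closed form `premium* = premium₀ +
  NMB(premium₀)` (each S$1 of premium reduces incremental NMB by exactly
  S$1 per patient) and verifies it against a bisection root on
  [0, 10⁶] S$ to S$0.01; a negative root is reported as 0 with a
  `not_reimbursable` flag.
* `evpi()` computes `E[max_s NMB_s] − max_s E[NMB_s]` per threshold.
  EVPPI has two estimators: nested Monte Carlo (outer draws of the target,
  inner draws of the rest; MC error from the outer variance) and a
  single-loop regression estimator that smooths the incremental NMB
  against the target. The regression smoother is `mgcv::gam` with a
  thin-plate spline (k = 10 by default, recorded in the output metadata)
  for continuous targets, and *exact within-group means* when the target
  has ≤ 10 unique values — so discrete priors are handled without
  smoothing bias. Negative estimates from MC noise are clipped to 0 with
  the raw value retained. Population scaling (`scale_to_population()`)
  requires an explicit effective population: none is defaulted, because
  no defensible default exists at the early stage.

## The synthetic parameter generator

`generate_parameter_table()` produces tables with the *structure* the
analysis assumes: every parameter the tree needs, cohort-specific
mortality with the hemorrhagic ≥ ischemic ordering, complication
utilities never above the well utility, sock RRs ≤ 1 by default, and
distributions/DSA ranges fitted by the rules above. Base values are drawn
uniformly within plausibility ranges chosen once from the post-stroke
literature's orders of magnitude (e.g. inpatient DVT probability under
IPC 6–12%, one-month stroke inpatient stay S$8,000–15,000, inpatient
utility 0.45–0.65). They are placeholders: the packaged defaults are
**not** transcribed estimates, and results under them are demonstrations
of the machinery, not reproductions of any published base case. What the
generator does *not* emulate: correlation between parameters (none is
modelled anywhere in the pipeline), heavy-tailed or skewed cost
uncertainty beyond the gamma family, cohort-specific utilities or costs,
and real-world parameter precision — so passing tests show the pipeline's
internal consistency on realistic structure, not calibration to real
data. `inst/extdata/params_template.csv` is the transcription path for
users holding actual estimates, after which the published CEAC levels
(40–50% cost-effective at the S$300 premium, above 90% at S$150, under
the conservative scenario) become reproducible targets rather than
structural illustrations.

## Numerical choices and degenerate inputs

* Pathway probabilities must sum to 1 within 1e−12; expected values are
  exact probability-weighted sums (no simulation in the base case).
* The microsimulation cross-check (`microsimulate()`) draws patients
  through the same chance nodes and agrees with enumeration within
  Monte-Carlo error; it exists to catch structural errors in the
  enumeration, and the test suite compares the two within 3 standard
  errors across seeded tables at n = 200,000 patients.
* Monotonicity: lowering a *non-fatal* adverse-event probability (DVT,
  PE, recurrences, ankle contracture) never lowers expected QALYs nor
  raises expected cost, given non-negative event costs and complication
  utilities at most the well utility. Mortality probabilities are
  excluded from this property on purpose: longer survival accrues more
  monthly care cost, so the cost half of the claim cannot hold for them
  in any model with positive post-discharge costs.
* Problem sizes used in the shipped tests and acceptance script — 5,000
  PSA draws, 200,000 microsimulated patients, 100 random tables for the
  threshold-linearity check, outer×inner loops of a few hundred for
  nested EVPPI — were chosen as the package's standard demonstration
  sizes; all scale linearly if larger runs are wanted.

## Limitations

The model inherits the limitations of any early evaluation: a 1-year
horizon (no long-term sequelae of contracture or recurrent stroke), no
interaction with pharmacological DVT prophylaxis, a healthcare-system
(not societal) perspective, no parameter correlation, and placeholder
default values. EVSI/ENBS are deliberately out of scope — the module
interfaces (PSA samples carrying draws and per-strategy outcomes) do not
preclude adding them later.
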