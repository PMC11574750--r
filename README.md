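# vacomhta

Early health-economic evaluation of **VACOM**, a soft robotic sock that
combines intermittent pneumatic compression (IPC) with robotic ankle
mobilisation for post-stroke inpatients, against the current practice of
IPC plus manual ankle movement. The package is aimed at health-technology
assessment analysts and device innovators who want to run — and stress —
an early cost-utility model before a first clinical trial: what the device
is worth, which parameters drive that value, what price premium the
evidence supports, and whether more research is worth paying for.

## The model

A two-period decision tree over a 1-year horizon from a healthcare-system
perspective (costs in 2019 Singapore dollars):

* **Inpatient stay (month 1):** chance nodes for deep vein thrombosis
  (DVT), pulmonary embolism given DVT, and inpatient death (assumed on day
  15 of the stay). Ischemic (`is`) and hemorrhagic (`ha`) stroke cohorts
  are modelled separately because their baseline mortality differs.
* **Post-discharge (months 2–12):** one mutually exclusive outcome per
  patient — well, recurrent stroke, recurrent DVT, recurrent PE, ankle
  contracture, or death — occurring at the start of month 7.

The sock acts through relative risks on DVT (`rr_dvt_vac_ipc`) and ankle
contracture (`rr_ankcon_vac`), diluted by the compliance rate:
`RR_eff = c·RR + (1 − c)`. Utilities are combined multiplicatively for
comorbid states (`u = u_base × u_DVT × u_PE`), and QALYs are time-weighted
utilities (months as 1/12 year). Expected cost `C_s` and QALYs `E_s` per
strategy come from exact enumeration of all 21 pathways, cross-checked by
microsimulation. Decision statistics are the standard ones:

* `ICER = ΔC/ΔE`, `NMB = λ·ΔE − ΔC` at ceiling threshold λ = S$75,000/QALY;
* PSA with beta/gamma/lognormal parameter distributions and CEACs;
* one-way DSA tornado ranked by percent change in incremental NMB;
* threshold analysis: the maximum price premium with `NMB ≥ 0`
  (closed form `premium* = premium₀ + NMB(premium₀)`, verified by bisection);
* `EVPI = E[max_s NMB_s] − max_s E[NMB_s]` and per-parameter EVPPI by
  nested Monte Carlo and regression estimators.

Parameter values ship as a **synthetic placeholder table** generated
within literature-plausible ranges (`default_parameter_table()`); a
transcription template (`inst/extdata/params_template.csv`) lets you drop
in real estimates.

## Worked example

```r
library(vacomhta)

tab <- default_parameter_table()                   # synthetic Table-S1 surrogate
sc  <- builtin_scenarios()$conservative_150        # RR ankle contracture 0.9, premium S$150

vac <- build_and_evaluate("is", "VACOM", tab, sc)
ipc <- build_and_evaluate("is", "IPC_manual", tab, sc)
incremental(vac, ipc, threshold = 75000)
#> incremental_result: dCost S$13.31, dQALY 0.001461, ICER S$9106/QALY,
#>   NMB S$96.30 at S$75000/QALY [cost_effective]

psa <- run_psa("is", tab, sc, n = 5000, seed = 1)
ceac(psa, 75000)
#>   threshold prob_ce
#> 1     75000   0.536

max_premium("is", tab, sc)
#> [1] 246.2997  (attr not_reimbursable: FALSE)
```

Read: at a S$150 premium under the conservative effectiveness assumption,
the sock costs S$13 more per ischemic patient, gains 0.0015 QALYs, and has
a positive net monetary benefit of S$96 — it remains reimbursable up to a
premium of about S$246. The CEAC value is the share of 5,000 probabilistic
draws with positive NMB at S$75,000/QALY. `one_way_dsa()`, `evpi()` and
`evppi_regression()` give the tornado and value-of-information views, and
`run_analysis()` writes the full CSV output set plus a reproducibility
manifest (also available from the shell via
`inst/scripts/vacom_cea.R`).

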