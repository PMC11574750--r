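name: conservative_150
rr_ankcon_vac: 0.9
price_premium: 150.0
cohort: both
threshold: 75000.0
timing:
  horizon_months: 12
  inpatient_months: 1
  inpatient_death_day: 15
  postdischarge_event_month: 7
seed: 1
n_psa: 5000
discount_rate: 0.0
effects:
  prob_dvt: rr_dvt_vac_ipc
  prob_ankcon: rr_ankcon_vac
param_overrides: []
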