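# Transcription template: replace base_value with your point estimates and
# either fill se (standard error; distributions are then fitted by role:
# beta for probabilities/utilities/QALYs, gamma for costs, lognormal for
# relative risks) or leave se blank for the default 20%-of-base rule.
# dsa_low/dsa_high may be left blank (2.5th/97.5th percentiles are derived).
name,cohort,role,base_value,se,dsa_low,dsa_high
prob_dvt,both,probability,0.111994419889525,,,
prob_pe_dvt,both,probability,0.27974670608528,,,
prob_death_inpat,is,probability,0.0514276938862167,,,
prob_death_inpat,ha,probability,0.254850604757667,,,
prob_recstroke,both,probability,0.0309687140234746,,,
prob_recdvt,both,probability,0.0488633071514778,,,
prob_recpe,both,probability,0.0133958277583588,,,
prob_ankcon,both,probability,0.229912851424888,,,
prob_death_postdis,is,probability,0.101530336921569,,,
prob_death_postdis,ha,probability,0.101530336921569,,,
prob_compliance_vac,both,probability,0.607545074843801,,,
rr_dvt_vac_ipc,both,relative_risk,0.749452317971736,,,
rr_ankcon_vac,both,relative_risk,0.482239595381543,,,
cost_device,both,cost,427.918209601194,,,
cost_inpat_stay,both,cost,10698.9488091785,,,
cost_dvt,both,cost,3374.50711731799,,,
cost_pe,both,cost,7023.40454026125,,,
cost_recstroke,both,cost,10914.8125885986,,,
cost_recdvt,both,cost,3025.62611387111,,,
cost_recpe,both,cost,10263.5897356085,,,
cost_ankcon,both,cost,3446.86124753207,,,
cost_postdis_monthly,both,cost,355.046763899736,,,
qaly_ndnp_inpat_death,both,whole_pathway_qaly,0.0199695436526345,,,
qaly_ndnp_1_12m_well,both,whole_pathway_qaly,0.724728797140415,,,
qaly_ndnp_1_12m_recstroke,both,whole_pathway_qaly,0.613321476415149,,,
qaly_ndnp_1_12m_recdvt,both,whole_pathway_qaly,0.664483289801865,,,
qaly_ndnp_1_12m_recpe,both,whole_pathway_qaly,0.674344200824271,,,
qaly_ndnp_1_12m_ankcon,both,whole_pathway_qaly,0.616088496768498,,,
qaly_ndnp_1_12m_death,both,whole_pathway_qaly,0.351509706073557,,,
qaly_dnp_inpat_death,both,whole_pathway_qaly,0.0196298939201778,,,
qaly_dnp_1_12m_well,both,whole_pathway_qaly,0.724040062960711,,,
qaly_dnp_1_12m_recstroke,both,whole_pathway_qaly,0.612632742235445,,,
qaly_dnp_1_12m_recdvt,both,whole_pathway_qaly,0.663794555622161,,,
qaly_dnp_1_12m_recpe,both,whole_pathway_qaly,0.673655466644567,,,
qaly_dnp_1_12m_ankcon,both,whole_pathway_qaly,0.615399762588794,,,
qaly_dnp_1_12m_death,both,whole_pathway_qaly,0.350820971893853,,,
qaly_dp_inpat_death,both,whole_pathway_qaly,0.0185131881187488,,,
qaly_dp_1_12m_well,both,whole_pathway_qaly,0.721775631752258,,,
qaly_dp_1_12m_recstroke,both,whole_pathway_qaly,0.610368311026992,,,
qaly_dp_1_12m_recdvt,both,whole_pathway_qaly,0.661530124413708,,,
qaly_dp_1_12m_recpe,both,whole_pathway_qaly,0.671391035436114,,,
qaly_dp_1_12m_ankcon,both,whole_pathway_qaly,0.613135331380341,,,
qaly_dp_1_12m_death,both,whole_pathway_qaly,0.3485565406854,,,
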