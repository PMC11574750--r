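# Synthetic default parameter table (both cohorts: is = ischemic, ha = hemorrhagic).
# Base values are placeholders drawn from literature-plausible ranges by
# generate_parameter_table(generator_profile(seed = 20190)); they are NOT
# estimates transcribed from any published supplement.
# Columns: name, cohort {is|ha|both}, role {probability|relative_risk|cost|utility|whole_pathway_qaly},
# base_value, dist_family {beta|gamma|lognormal|fixed}, dist_param1, dist_param2, dsa_low, dsa_high.
name,cohort,role,base_value,dist_family,dist_param1,dist_param2,dsa_low,dsa_high
prob_dvt,both,probability,0.111994419889525,beta,22.0881450828724,175.137262260287,0.0719763814674678,0.15945100289044
prob_pe_dvt,both,probability,0.27974670608528,beta,17.7265856417827,45.6399715193188,0.177187489895138,0.395468734243894
prob_death_inpat,is,probability,0.0514276938862167,beta,23.6628799589584,436.456525964866,0.0331824953563534,0.0733571647715962
prob_death_inpat,ha,probability,0.254850604757667,beta,18.3738842763007,53.7228026975133,0.161837439635957,0.360737351357123
prob_recstroke,both,probability,0.0309687140234746,beta,24.1948134353897,757.07151286572,0.0200062499992532,0.0441995814208592
prob_recdvt,both,probability,0.0488633071514778,beta,23.7295540140616,461.901800009914,0.0315328071785647,0.0697044132901217
prob_recpe,both,probability,0.0133958277583588,beta,24.6517084782827,1815.60101221681,0.00866262868943399,0.0191280030539146
prob_ankcon,both,probability,0.229912851424888,beta,19.0222658629529,63.7145874493443,0.146355233048475,0.325826703910181
prob_death_postdis,is,probability,0.101530336921569,beta,22.3602112400392,197.871612252403,0.0652985291250915,0.144602655851856
prob_death_postdis,ha,probability,0.101530336921569,beta,22.3602112400392,197.871612252403,0.0652985291250915,0.144602655851856
prob_compliance_vac,both,probability,0.607545074843801,beta,9.20382805406116,5.94538216120961,0.359957388446453,0.828268283596572
rr_dvt_vac_ipc,both,relative_risk,0.749452317971736,lognormal,-0.30802293848985,0.198042200435365,0.498486625832191,1.08343076633262
rr_ankcon_vac,both,relative_risk,0.482239595381543,lognormal,-0.7489245591606,0.198042200435365,0.320754213416806,0.697140033930565
cost_device,both,cost,427.918209601194,gamma,25,0.058422379415214,276.926102801218,611.240041080111
cost_inpat_stay,both,cost,10698.9488091785,gamma,25,0.00233667815837689,6923.79555559649,15282.4202450534
cost_dvt,both,cost,3374.50711731799,gamma,25,0.00740848933810211,2183.80308177294,4820.15913960961
cost_pe,both,cost,7023.40454026125,gamma,25,0.00355952727152323,4545.17710181947,10032.2584629255
cost_recstroke,both,cost,10914.8125885986,gamma,25,0.00229046534670825,7063.49121198476,15590.7609102553
cost_recdvt,both,cost,3025.62611387111,gamma,25,0.00826275258710468,1958.0256914722,4321.81615234183
cost_recpe,both,cost,10263.5897356085,gamma,25,0.00243579494543365,6642.0541179623,14660.551644833
cost_ankcon,both,cost,3446.86124753207,gamma,25,0.00725297544770618,2230.62685989734,4923.51006165985
cost_postdis_monthly,both,cost,355.046763899736,gamma,25,0.0704132597222035,229.767545369408,507.150183568233
qaly_ndnp_inpat_death,both,whole_pathway_qaly,0.0199695436526345,beta,24.4807918650315,1201.42563298218,0.0129088176755409,0.0285096875203411
qaly_ndnp_1_12m_well,both,whole_pathway_qaly,0.724728797140415,beta,6.15705127434922,2.33861123919142,0.402124240391887,0.948963701090778
qaly_ndnp_1_12m_recstroke,both,whole_pathway_qaly,0.613321476415149,beta,9.05364161320613,5.70801595359631,0.362561907686465,0.835038726168206
qaly_ndnp_1_12m_recdvt,both,whole_pathway_qaly,0.664483289801865,beta,7.72343446515151,3.89978403211797,0.383659856731182,0.891994999208822
qaly_ndnp_1_12m_recpe,both,whole_pathway_qaly,0.674344200824271,beta,7.46705077856895,3.60600474625317,0.387238928132421,0.90221194427523
qaly_ndnp_1_12m_ankcon,both,whole_pathway_qaly,0.616088496768498,beta,8.98169908401905,5.59688683526005,0.363795493519768,0.838260856668137
qaly_ndnp_1_12m_death,both,whole_pathway_qaly,0.351509706073557,beta,15.8607476420875,29.2610437851128,0.220728642338493,0.494761265504309
qaly_dnp_inpat_death,both,whole_pathway_qaly,0.0196298939201778,beta,24.4896227580754,1223.0781357667,0.0126895053917375,0.0280250381010625
qaly_dnp_1_12m_well,both,whole_pathway_qaly,0.724040062960711,beta,6.17495836302151,2.35351772402146,0.401966924291752,0.948398911617158
qaly_dnp_1_12m_recstroke,both,whole_pathway_qaly,0.612632742235445,beta,9.07154870187842,5.7359339487829,0.36225342691457,0.834234560440898
qaly_dnp_1_12m_recdvt,both,whole_pathway_qaly,0.663794555622161,beta,7.74134155382381,3.92091371515472,0.383403143422116,0.891270739485549
qaly_dnp_1_12m_recpe,both,whole_pathway_qaly,0.673655466644567,beta,7.48495786724125,3.62600053486796,0.386994971915145,0.901507902263793
qaly_dnp_1_12m_ankcon,both,whole_pathway_qaly,0.615399762588794,beta,8.99960617269135,5.62439389977021,0.363489310505533,0.837460145656321
qaly_dnp_1_12m_death,both,whole_pathway_qaly,0.350820971893853,beta,15.8786547307598,29.3827634935879,0.22031647351603,0.493815083980977
qaly_dp_inpat_death,both,whole_pathway_qaly,0.0185131881187488,beta,24.5186571089125,1299.87004091776,0.0119683858611374,0.0264315366769853
qaly_dp_1_12m_well,both,whole_pathway_qaly,0.721775631752258,beta,6.2338335744413,2.4029689168085,0.401439236463094,0.946525205966507
qaly_dp_1_12m_recstroke,both,whole_pathway_qaly,0.610368311026992,beta,9.13042391329821,5.8284521429236,0.361235235450024,0.831584666486824
qaly_dp_1_12m_recdvt,both,whole_pathway_qaly,0.661530124413708,beta,7.8002167652436,3.99095717737417,0.382553145139407,0.888880086852156
qaly_dp_1_12m_recpe,both,whole_pathway_qaly,0.671391035436114,beta,7.54383307866104,3.69229114775317,0.386186384036512,0.899182800999018
qaly_dp_1_12m_ankcon,both,whole_pathway_qaly,0.613135331380341,beta,9.05848138411114,5.71555123233904,0.362478590042834,0.834821467137403
qaly_dp_1_12m_death,both,whole_pathway_qaly,0.3485565406854,beta,15.9375299421796,29.7868449636538,0.218960476151034,0.490703178992561
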