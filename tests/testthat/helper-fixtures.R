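# Shared fixtures: a small decomposed-utility parameter set with round
# numbers, plus an independent brute-force enumeration oracle written
# directly from the clinical pathway rules (no calls into the package's
# tree builder).

toy_values <- function(...) {
  v <- list(
    prob_dvt = 0.2, prob_pe_dvt = 0.25, prob_death_inpat = 0.1,
    prob_recstroke = 0.05, prob_recdvt = 0.03, prob_recpe = 0.01,
    prob_ankcon = 0.3, prob_death_postdis = 0.08,
    prob_compliance_vac = 0.8,
    rr_dvt_vac_ipc = 0.7, rr_ankcon_vac = 0.5,
    cost_device = 500, cost_inpat_stay = 8000, cost_dvt = 2000,
    cost_pe = 6000, cost_recstroke = 12000, cost_recdvt = 2000,
    cost_recpe = 6000, cost_ankcon = 3000, cost_postdis_monthly = 200,
    util_inpat = 0.5, util_dvt = 0.95, util_pe = 0.9,
    util_postdis_well = 0.7, util_postdis_recstroke = 0.45,
    util_postdis_recdvt = 0.6, util_postdis_recpe = 0.55,
    util_postdis_ankcon = 0.55)
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

role_of <- function(name) {
  if (startsWith(name, "prob_")) "probability"
  else if (startsWith(name, "rr_")) "relative_risk"
  else if (startsWith(name, "cost_")) "cost"
  else if (startsWith(name, "qaly_")) "whole_pathway_qaly"
  else "utility"
}

toy_table <- function(values = toy_values(), se_frac = 0) {
  df <- data.frame(name = names(values), cohort = "both",
                   role = vapply(names(values), role_of, ""),
                   base_value = unlist(values),
                   se = se_frac * abs(unlist(values)),
                   stringsAsFactors = FALSE)
  parameter_table(df)
}

toy_scenario <- function(premium = 150, rr_ankcon_vac = NULL, seed = 1L,
                         n_psa = 500L, threshold = 75000) {
  scenario_config(name = "custom", rr_ankcon_vac = rr_ankcon_vac,
                  price_premium = premium, threshold = threshold,
                  seed = seed, n_psa = n_psa)
}

# Brute-force oracle: exhaustively enumerate the 21 clinical pathways with
# inline arithmetic. 30-day months for the day-15 half-stay rule, 1/12-year
# months for QALY weights; post-discharge events at the start of month 7.
oracle_eval <- function(v, premium, vacom) {
  err <- function(rr) {
    if (vacom) v$prob_compliance_vac * rr + (1 - v$prob_compliance_vac) else 1
  }
  p_dvt <- min(1, v$prob_dvt * err(v$rr_dvt_vac_ipc))
  p_ak <- min(1, v$prob_ankcon * err(v$rr_ankcon_vac))
  dev <- v$cost_device + if (vacom) premium else 0
  states <- list(
    list(p = 1 - p_dvt, ev = 0, u = v$util_inpat),
    list(p = p_dvt * (1 - v$prob_pe_dvt), ev = v$cost_dvt,
         u = v$util_inpat * v$util_dvt),
    list(p = p_dvt * v$prob_pe_dvt, ev = v$cost_dvt + v$cost_pe,
         u = v$util_inpat * v$util_dvt * v$util_pe))
  oc <- list(well = 0, recstroke = v$cost_recstroke,
             recdvt = v$cost_recdvt, recpe = v$cost_recpe,
             ankcon = v$cost_ankcon, death = 0)
  ou <- list(well = v$util_postdis_well,
             recstroke = v$util_postdis_recstroke,
             recdvt = v$util_postdis_recdvt, recpe = v$util_postdis_recpe,
             ankcon = v$util_postdis_ankcon, death = 0)
  op <- c(recstroke = v$prob_recstroke, recdvt = v$prob_recdvt,
          recpe = v$prob_recpe, ankcon = p_ak,
          death = v$prob_death_postdis)
  op <- c(well = 1 - sum(op), op)
  EC <- 0; EQ <- 0
  for (s in states) {
    EC <- EC + s$p * v$prob_death_inpat *
      (dev + s$ev + v$cost_inpat_stay * 15 / 30)
    EQ <- EQ + s$p * v$prob_death_inpat * (15 / 365 * s$u)
    for (o in names(op)) {
      p <- s$p * (1 - v$prob_death_inpat) * op[[o]]
      months <- if (o == "death") 5 else 11
      EC <- EC + p * (dev + s$ev + v$cost_inpat_stay + oc[[o]] +
                        months * v$cost_postdis_monthly)
      q <- 1 / 12 * s$u + 5 / 12 * v$util_postdis_well +
        if (o == "death") 0 else 6 / 12 * ou[[o]]
      EQ <- EQ + p * q
    }
  }
  list(cost = EC, qaly = EQ)
}
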