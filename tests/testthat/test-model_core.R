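test_that("effective relative risk is the compliance-weighted mixture", {
  expect_equal(effective_relative_risk(0.3, 1.0), 0.3)
  expect_equal(effective_relative_risk(0.3, 0.0), 1.0)
  expect_equal(effective_relative_risk(0.5, 0.8), 0.6)
  # monotone increasing in compliance when rr < 1 means lower effective RR
  comp <- seq(0, 1, by = 0.1)
  expect_true(all(diff(effective_relative_risk(0.3, comp)) < 0))
  expect_error(effective_relative_risk(Inf, 0.5), "finite")
  expect_error(effective_relative_risk(0.5, 1.2), "\\[0,1\\]")
  expect_error(effective_relative_risk(-1, 0.5), "> 0")
})

test_that("arm probability multiplies and clips at 1", {
  expect_equal(arm_probability(0.10, 1.0), 0.10)
  expect_equal(arm_probability(0.10, 0.3), 0.03)
  expect_equal(arm_probability(0.60, 2.0), 1.0)
  expect_error(arm_probability(1.2, 1), "\\[0,1\\]")
})

test_that("comorbidity utilities combine multiplicatively and never exceed inputs", {
  expect_equal(combined_utility(0.8, list(0.9)), 0.72)
  expect_equal(combined_utility(0.7), 0.7)
  expect_equal(combined_utility(0.8, list(0.9, 0.5)), 0.36)
  expect_error(combined_utility(1.1), "\\[0,1\\]")
  expect_error(combined_utility(0.5, list(-0.1)), "\\[0,1\\]")
  set.seed(42)
  for (i in 1:25) {
    us <- runif(sample(1:4, 1))
    base <- runif(1)
    expect_lte(combined_utility(base, as.list(us)), min(c(base, us)))
  }
})

test_that("pathway QALY follows the timing rules and passes whole-pathway values through", {
  u <- toy_values()
  # inpatient death on day 15 at utility 0.5
  expect_equal(pathway_qaly("ndnp", NA, list(util_inpat = 0.5)), 0.5 * 15 / 365)
  # survivor well all year at full health accrues exactly one QALY
  full <- list(util_inpat = 1, util_dvt = 1, util_pe = 1,
               util_postdis_well = 1)
  expect_equal(pathway_qaly("ndnp", "well", full), 1.0)
  # whole-pathway mode passes the supplied value through untouched
  expect_equal(pathway_qaly("ndnp", "well", list(qaly_ndnp_1_12m_well = 0.62)),
               0.62)
  # post-discharge death truncates accrual at the start of month 7
  expect_equal(pathway_qaly("ndnp", "death", u),
               u$util_inpat / 12 + 5 / 12 * u$util_postdis_well)
  # comorbidity multipliers act on the inpatient month
  expect_equal(pathway_qaly("dp", NA, u),
               15 / 365 * u$util_inpat * u$util_dvt * u$util_pe)
  expect_error(pathway_qaly("ndnp", "well", list(util_inpat = 0.5)),
               "util_postdis_well")
})

test_that("pathway cost sums device, stay, event and monthly components", {
  costs <- list(cost_device = 500, cost_inpat_stay = 8000, cost_dvt = 0,
                cost_pe = 0, cost_recstroke = 0, cost_recdvt = 0,
                cost_recpe = 0, cost_ankcon = 0, cost_postdis_monthly = 0)
  expect_equal(pathway_cost("ndnp", "well", costs, strategy("VACOM", 150)),
               8650)
  expect_equal(pathway_cost("ndnp", "well", costs, strategy("IPC_manual")),
               8500)
  # day-15 death accrues exactly half the one-month stay
  expect_equal(pathway_cost("ndnp", NA, costs, strategy("IPC_manual")), 4500)
  # independent day-by-day accrual of the stay gives the same half-stay
  per_day <- 8000 / 30
  expect_equal(pathway_cost("ndnp", NA, costs, 0), 500 + 15 * per_day)
  v <- toy_values()
  # full composition on a complication pathway
  expect_equal(pathway_cost("dp", "ankcon", v, 0),
               v$cost_device + v$cost_inpat_stay + v$cost_dvt + v$cost_pe +
                 v$cost_ankcon + 11 * v$cost_postdis_monthly)
  expect_error(pathway_cost("ndnp", "well", costs[-2], 0), "cost_inpat_stay")
})

test_that("tree evaluation matches the brute-force enumeration oracle", {
  v <- toy_values()
  tab <- toy_table(v)
  sc <- toy_scenario(premium = 150)
  for (arm in c("VACOM", "IPC_manual")) {
    res <- build_and_evaluate("is", arm, tab, sc)
    orc <- oracle_eval(v, 150, arm == "VACOM")
    expect_equal(res$expected_cost, orc$cost, tolerance = 1e-12)
    expect_equal(res$expected_qaly, orc$qaly, tolerance = 1e-12)
    expect_equal(sum(res$pathways$probability), 1, tolerance = 1e-12)
  }
  # 3-parameter toy: p_dvt 0.2, inpatient death 0.1, everything else well
  v3 <- toy_values(prob_pe_dvt = 0, prob_recstroke = 0, prob_recdvt = 0,
                   prob_recpe = 0, prob_ankcon = 0, prob_death_postdis = 0)
  r3 <- build_and_evaluate("is", "IPC_manual", toy_table(v3), sc)
  o3 <- oracle_eval(v3, 0, FALSE)
  expect_equal(r3$expected_cost, o3$cost, tolerance = 1e-12)
  expect_equal(r3$expected_qaly, o3$qaly, tolerance = 1e-12)
})

test_that("degenerate tree collapses to a single well pathway", {
  v <- toy_values(prob_dvt = 0, prob_pe_dvt = 0, prob_death_inpat = 0,
                  prob_recstroke = 0, prob_recdvt = 0, prob_recpe = 0,
                  prob_ankcon = 0, prob_death_postdis = 0)
  sc <- toy_scenario(premium = 0)
  for (arm in c("VACOM", "IPC_manual")) {
    res <- build_and_evaluate("is", arm, toy_table(v), sc)
    live <- res$pathways[res$pathways$probability > 0, ]
    expect_equal(nrow(live), 1)
    expect_equal(live$pathway, "ndnp_1_12m_well")
    expect_equal(live$probability, 1)
    expect_equal(res$expected_qaly,
                 v$util_inpat / 12 + 11 / 12 * v$util_postdis_well)
  }
})

test_that("identical effects and zero premium make the strategies coincide", {
  v <- toy_values(rr_dvt_vac_ipc = 1, rr_ankcon_vac = 1)
  sc <- toy_scenario(premium = 0)
  vac <- build_and_evaluate("is", "VACOM", toy_table(v), sc)
  ipc <- build_and_evaluate("is", "IPC_manual", toy_table(v), sc)
  expect_identical(vac$expected_cost, ipc$expected_cost)
  expect_identical(vac$expected_qaly, ipc$expected_qaly)
})

test_that("post-discharge probabilities summing beyond 1 are rejected", {
  v <- toy_values(prob_recstroke = 0.5, prob_ankcon = 0.6)
  expect_error(build_and_evaluate("is", "IPC_manual", toy_table(v),
                                  toy_scenario()),
               "residual well branch negative|more than 1")
})

test_that("whole-pathway and decomposed evaluation agree after conversion", {
  tab <- toy_table(toy_values(), se_frac = 0.15)
  wp <- as_whole_pathway(tab)
  sc <- toy_scenario(premium = 150)
  for (arm in c("VACOM", "IPC_manual")) {
    a <- build_and_evaluate("is", arm, tab, sc)
    b <- build_and_evaluate("is", arm, wp, sc)
    expect_equal(a$expected_cost, b$expected_cost, tolerance = 1e-12)
    expect_equal(a$expected_qaly, b$expected_qaly, tolerance = 1e-12)
  }
})

test_that("microsimulation converges to the exact enumeration", {
  tab <- toy_table()
  sc <- toy_scenario()
  # degenerate tree: any n reproduces the single pathway exactly
  v0 <- toy_values(prob_dvt = 0, prob_death_inpat = 0, prob_recstroke = 0,
                   prob_recdvt = 0, prob_recpe = 0, prob_ankcon = 0,
                   prob_death_postdis = 0)
  ms0 <- microsimulate("is", "IPC_manual", toy_table(v0), sc, 10, seed = 1)
  ex0 <- build_and_evaluate("is", "IPC_manual", toy_table(v0), sc)
  expect_equal(ms0$expected_cost, ex0$expected_cost)
  expect_equal(ms0$expected_qaly, ex0$expected_qaly)
  expect_equal(ms0$se_cost, 0)
  # n = 1 returns one pathway's exact cost and QALY
  ms1 <- microsimulate("is", "VACOM", tab, sc, 1, seed = 7)
  ex <- build_and_evaluate("is", "VACOM", tab, sc)
  hit <- vapply(seq_len(nrow(ex$pathways)), function(i) {
    isTRUE(all.equal(ms1$expected_cost, ex$pathways$cost[i])) &&
      isTRUE(all.equal(ms1$expected_qaly, ex$pathways$qaly[i]))
  }, TRUE)
  expect_true(any(hit))
  # large-n agreement within 3 Monte-Carlo standard errors
  ms <- microsimulate("is", "VACOM", tab, sc, 200000, seed = 11)
  expect_lt(abs(ms$expected_cost - ex$expected_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$expected_qaly - ex$expected_qaly), 3 * ms$se_qaly)
})

test_that("lowering a non-fatal adverse-event probability never hurts", {
  sc <- toy_scenario(premium = 0)
  base <- toy_values()
  ref <- build_and_evaluate("is", "IPC_manual", toy_table(base), sc)
  sweep <- c("prob_dvt", "prob_pe_dvt", "prob_recstroke", "prob_recdvt",
             "prob_recpe", "prob_ankcon")
  for (nm in sweep) {
    v <- base
    v[[nm]] <- v[[nm]] / 2
    res <- build_and_evaluate("is", "IPC_manual", toy_table(v), sc)
    expect_gte(res$expected_qaly, ref$expected_qaly)
    expect_lte(res$expected_cost, ref$expected_cost)
  }
})

test_that("generated tables always produce a valid, fully enumerated tree", {
  sc <- toy_scenario()
  for (s in 1:25) {
    tab <- generate_parameter_table(generator_profile(seed = s))
    for (cohort in c("is", "ha")) {
      res <- build_and_evaluate(cohort, "VACOM", tab, sc)
      expect_equal(sum(res$pathways$probability), 1, tolerance = 1e-12)
      expect_true(all(res$pathways$probability >= 0))
      expect_true(all(res$pathways$cost >= 0))
      expect_true(all(res$pathways$qaly >= 0 & res$pathways$qaly <= 1))
    }
  }
})
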