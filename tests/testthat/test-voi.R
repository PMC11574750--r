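# Hand-built psa_samples object for discrete toy cases.
mk_psa <- function(draws, cost_v, cost_i, qaly_v, qaly_i,
                   scenario = toy_scenario()) {
  structure(list(draws = draws,
                 cost = cbind(VACOM = cost_v, IPC_manual = cost_i),
                 qaly = cbind(VACOM = qaly_v, IPC_manual = qaly_i),
                 cohort = "is", scenario = scenario),
            class = "psa_samples")
}

test_that("EVPI is zero without uncertainty and positive when decisions flip", {
  # degenerate draws: every parameter fixed
  tab <- toy_table(toy_values(), se_frac = 0)
  psa <- run_psa("is", tab, toy_scenario(n_psa = 50))
  out <- evpi(psa, c(0, 75000, 150000))
  expect_equal(out$evpi, c(0, 0, 0))
  # two equally likely states with incremental NMB +100 / -100: EVPI 50
  n <- 100
  dn <- rep(c(100, -100), each = n / 2)
  psa2 <- mk_psa(matrix(0, n, 1, dimnames = list(NULL, "x")),
                 cost_v = -dn, cost_i = rep(0, n),
                 qaly_v = rep(0, n), qaly_i = rep(0, n))
  # brute force over the 2-outcome distribution: E[max] - max[E] = 50 - 0
  expect_equal(evpi(psa2, 75000)$evpi, 50)
  # one strategy better in every draw: EVPI 0
  psa3 <- mk_psa(matrix(0, 4, 1, dimnames = list(NULL, "x")),
                 cost_v = c(1, 2, 3, 4), cost_i = c(5, 6, 7, 8),
                 qaly_v = rep(1, 4), qaly_i = rep(1, 4))
  expect_equal(evpi(psa3, c(0, 75000))$evpi, c(0, 0))
})

test_that("EVPI is continuous in the threshold on a fixed draw set", {
  tab <- toy_table(toy_values(), se_frac = 0.2)
  psa <- run_psa("is", tab, toy_scenario(n_psa = 500))
  grid <- seq(0, 150000, by = 2500)
  ev <- evpi(psa, grid)$evpi
  expect_true(all(ev >= 0))
  # each draw's max-NMB is piecewise linear in lambda with slope at most
  # max |dQALY|; adjacent grid values cannot jump more than that bound
  max_slope <- max(abs(psa$qaly)) + 1
  expect_true(all(abs(diff(ev)) <= max_slope * diff(grid)[1]))
})

test_that("nested-MC EVPPI: fixed target is exactly zero, sensitive target approaches EVPI", {
  tab <- toy_table(toy_values(), se_frac = 0.15)
  sc <- toy_scenario(n_psa = 500)
  # fixed target short-circuits without simulation
  fixed_tab <- toy_table(toy_values(), se_frac = 0)
  z <- evppi_nested_mc("is", fixed_tab, sc, "prob_ankcon")
  expect_identical(z$evppi, 0)
  expect_identical(z$n_outer, 0L)
  # model where only one parameter is uncertain: its EVPPI equals EVPI
  df <- as.data.frame(fixed_tab)
  i <- which(df$name == "prob_ankcon")
  fit <- moments_to_dist("probability", df$base_value[i], 0.08)
  df$dist_family[i] <- fit$dist_family
  df$dist_param1[i] <- fit$dist_param1; df$dist_param2[i] <- fit$dist_param2
  one_unc <- parameter_table(df)
  psa <- run_psa("is", one_unc, sc, n = 2000, seed = 5)
  ev <- evpi(psa, sc$threshold)$evpi
  np <- evppi_nested_mc("is", one_unc, sc, "prob_ankcon",
                        n_outer = 500, n_inner = 2, seed = 9)
  expect_lt(abs(np$evppi - ev), 2 * np$mc_error + 0.05 * max(ev, 1))
})

test_that("EVPPI over the full parameter set equals EVPI on the same draws", {
  tab <- toy_table(toy_values(), se_frac = 0.15)
  sc <- toy_scenario(n_psa = 400)
  psa <- run_psa("is", tab, sc)
  ev <- evpi(psa, sc$threshold)$evpi
  all_params <- colnames(psa$draws)
  np <- evppi_nested_mc("is", tab, sc, all_params,
                        outer_draws = psa$draws, n_inner = 1)
  expect_equal(np$evppi, ev, tolerance = 1e-9)
})

test_that("both EVPPI estimators match the brute-force oracle on a 2-point prior", {
  # all parameters fixed except prob_ankcon, which takes two equally
  # likely values; the inner evaluation is then deterministic.
  sc <- toy_scenario(premium = 600)
  fixed_tab <- toy_table(toy_values(), se_frac = 0)
  theta <- c(0.05, 0.45)
  # brute-force oracle over the discrete outer distribution
  dnmb <- vapply(theta, function(t) {
    tb <- toy_table(toy_values(prob_ankcon = t))
    vac <- build_and_evaluate("is", "VACOM", tb, sc)
    ipc <- build_and_evaluate("is", "IPC_manual", tb, sc)
    incremental(vac, ipc, sc$threshold)$nmb
  }, 0)
  oracle <- mean(pmax(0, dnmb)) - max(0, mean(dnmb))
  expect_gt(oracle, 0)  # the decision flips between the two values

  np <- evppi_nested_mc("is", fixed_tab, sc, "prob_ankcon",
                        outer_draws = rep(theta, each = 50), n_inner = 1)
  expect_equal(np$evppi, oracle, tolerance = 1e-9)

  # regression estimator on a hand-built balanced PSA
  n <- 100
  th <- rep(theta, each = n / 2)
  res <- lapply(theta, function(t) {
    tb <- toy_table(toy_values(prob_ankcon = t))
    list(v = build_and_evaluate("is", "VACOM", tb, sc),
         i = build_and_evaluate("is", "IPC_manual", tb, sc))
  })
  pick <- function(f) unlist(lapply(res, f))[rep(1:2, each = n / 2)]
  psa <- mk_psa(matrix(th, ncol = 1,
                       dimnames = list(NULL, "prob_ankcon")),
                cost_v = pick(function(r) r$v$expected_cost),
                cost_i = pick(function(r) r$i$expected_cost),
                qaly_v = pick(function(r) r$v$expected_qaly),
                qaly_i = pick(function(r) r$i$expected_qaly),
                scenario = sc)
  rg <- evppi_regression(psa, "prob_ankcon", sc$threshold)
  expect_match(rg$method, "exact group means")
  expect_equal(rg$evppi, oracle, tolerance = 1e-9)
})

test_that("regression EVPPI is bounded by EVPI and vanishes for irrelevant targets", {
  tab <- toy_table(toy_values(), se_frac = 0.15)
  sc <- toy_scenario(n_psa = 1000)
  psa <- run_psa("is", tab, sc)
  ev <- evpi(psa, sc$threshold)$evpi
  for (nm in colnames(psa$draws)) {
    e <- evppi_regression(psa, nm, sc$threshold)$evppi
    expect_gte(e, 0)
    expect_lte(e, ev + max(1, 0.05 * ev))
  }
  # a target the NMB difference does not depend on carries ~no information:
  # cost_device enters both arms identically
  e0 <- evppi_regression(psa, "cost_device", sc$threshold)$evppi
  expect_lte(e0, 0.02 * max(ev, 1) + 1)
  # constant target column returns exactly 0
  psa0 <- psa
  psa0$draws[, "cost_device"] <- 400
  expect_equal(evppi_regression(psa0, "cost_device", sc$threshold)$evppi, 0)
})

test_that("population scaling requires an explicit population", {
  expect_equal(scale_to_population(10, 1000), 10000)
  expect_equal(scale_to_population(0, 5), 0)
  expect_equal(scale_to_population(12.5, 40000), 5e5)
  expect_error(scale_to_population(10), "explicit")
  expect_error(scale_to_population(10, 0), ">= 1")
})
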