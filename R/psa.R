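# Probabilistic sensitivity analysis: joint parameter resampling with both
# strategies evaluated on the same draw (common random numbers).

#' Run a probabilistic sensitivity analysis
#'
#' Samples `n` joint parameter draws for the cohort (see
#' [sample_psa_draws()]) and evaluates both strategies on every draw with
#' the vectorised pathway enumeration, so the two arms share common random
#' numbers. The result is the substrate for [ceac()], [evpi()] and the
#' EVPPI estimators.
#'
#' @param cohort `"is"` or `"ha"`.
#' @param params A [parameter_table()].
#' @param scenario A [scenario_config()]; supplies the price premium,
#'   scenario relative-risk override, timing, and defaults for `n` and
#'   `seed`.
#' @param n Number of draws (default `scenario$n_psa`).
#' @param seed Integer seed (default `scenario$seed`).
#' @return An object of class `psa_samples`: list with `draws` (n x p
#'   matrix), `cost` and `qaly` (n x 2 matrices with columns `VACOM`,
#'   `IPC_manual`), `cohort`, `scenario`.
#' @export
run_psa <- function(cohort, params, scenario, n = scenario$n_psa,
                    seed = scenario$seed) {
  if (n < 2) stop("a PSA needs at least 2 draws", call. = FALSE)
  tab <- apply_scenario(params, scenario)
  resolved <- resolve_parameters(tab, cohort)
  draws <- sample_psa_draws(resolved, n, seed)
  pv <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  names(pv) <- colnames(draws)
  vac <- expected_outcomes(pv, scenario$price_premium, TRUE, scenario$timing,
                           scenario$effects)
  ipc <- expected_outcomes(pv, 0, FALSE, scenario$timing, scenario$effects)
  structure(list(draws = draws,
                 cost = cbind(VACOM = vac$cost, IPC_manual = ipc$cost),
                 qaly = cbind(VACOM = vac$qaly, IPC_manual = ipc$qaly),
                 cohort = cohort, scenario = scenario),
            class = "psa_samples")
}

#' @export
print.psa_samples <- function(x, ...) {
  cat(sprintf(
    "psa_samples: %d draws x %d parameters (cohort %s, scenario '%s')\n",
    nrow(x$draws), ncol(x$draws), x$cohort, x$scenario$name))
  cat(sprintf("  mean dCost S$%.2f, mean dQALY %.6f\n",
              mean(x$cost[, "VACOM"] - x$cost[, "IPC_manual"]),
              mean(x$qaly[, "VACOM"] - x$qaly[, "IPC_manual"])))
  invisible(x)
}

# Incremental (VACOM - comparator) cost and QALY per draw.
psa_increments <- function(psa) {
  stopifnot(inherits(psa, "psa_samples"))
  list(delta_cost = psa$cost[, "VACOM"] - psa$cost[, "IPC_manual"],
       delta_qaly = psa$qaly[, "VACOM"] - psa$qaly[, "IPC_manual"])
}
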