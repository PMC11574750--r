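# Two-period decision tree: inpatient stay (month 1) then post-discharge
# (months 2-12). Inpatient chance nodes: DVT; PE given DVT; inpatient death.
# Survivors face one mutually exclusive post-discharge outcome; adverse
# events occur at the start of month 7.

tree_states <- function() c("ndnp", "dnp", "dp")

tree_outcomes <- function() {
  c("well", "recstroke", "recdvt", "recpe", "ankcon", "death")
}

# Pathway label: "<state>_inpat_death" or "<state>_1_12m_<outcome>".
pathway_label <- function(state, outcome = NA_character_) {
  ifelse(is.na(outcome), paste0(state, "_inpat_death"),
         paste0(state, "_1_12m_", outcome))
}

qaly_param_name <- function(state, outcome = NA_character_) {
  paste0("qaly_", pathway_label(state, outcome))
}

# All 21 whole-pathway QALY parameter names.
whole_pathway_qaly_names <- function() {
  c(vapply(tree_states(), qaly_param_name, "", outcome = NA_character_),
    as.vector(outer(tree_states(), tree_outcomes(),
                    function(s, o) qaly_param_name(s, o))))
}

#' Strategy descriptor
#'
#' @param name `"VACOM"` (the robotic sock) or `"IPC_manual"` (intermittent
#'   pneumatic compression plus manual ankle movement, the comparator).
#' @param price_premium Extra per-patient price in 2019 S$; must be 0 for
#'   the comparator.
#' @return An object of class `strategy`.
#' @export
strategy <- function(name = c("VACOM", "IPC_manual"), price_premium = 0) {
  name <- match.arg(name)
  price_premium <- as.numeric(price_premium)
  if (!is.finite(price_premium) || price_premium < 0) {
    stop("price_premium must be a finite value >= 0", call. = FALSE)
  }
  if (name == "IPC_manual" && price_premium != 0) {
    stop("the comparator carries no price premium", call. = FALSE)
  }
  structure(list(name = name, price_premium = price_premium),
            class = "strategy")
}

#' Effective relative risk under partial compliance
#'
#' Compliance is binary at the patient level; in this linear model the
#' cohort-level expectation is the compliance-weighted mixture of the full
#' treatment effect and no effect:
#' `compliance * rr + (1 - compliance) * 1`.
#'
#' @param rr Relative risk under full compliance, `> 0`.
#' @param compliance Probability of compliance, in `[0,1]`.
#' @return The effective relative risk (vectorised).
#' @examples
#' effective_relative_risk(0.5, 0.8)  # 0.6
#' @export
effective_relative_risk <- function(rr, compliance) {
  if (!all(is.finite(rr)) || !all(is.finite(compliance))) {
    stop("rr and compliance must be finite", call. = FALSE)
  }
  if (any(rr <= 0)) stop("rr must be > 0", call. = FALSE)
  if (any(compliance < 0 | compliance > 1)) {
    stop("compliance must lie in [0,1]", call. = FALSE)
  }
  compliance * rr + (1 - compliance)
}

#' Apply an effective relative risk to a baseline probability
#'
#' The comparator arm uses `rr_effective = 1`. The product is clipped at 1.
#'
#' @param baseline_prob Baseline probability, in `[0,1]`.
#' @param rr_effective Effective relative risk, `> 0`.
#' @return `min(1, baseline_prob * rr_effective)` (vectorised).
#' @export
arm_probability <- function(baseline_prob, rr_effective) {
  if (any(baseline_prob < 0 | baseline_prob > 1, na.rm = FALSE)) {
    stop("baseline_prob must lie in [0,1]", call. = FALSE)
  }
  if (any(rr_effective <= 0)) stop("rr_effective must be > 0", call. = FALSE)
  pmin(1, baseline_prob * rr_effective)
}

#' Multiplicative comorbidity adjustment of utilities
#'
#' Combines a base health-state utility with comorbidity utilities by
#' multiplication, the standard comorbidity adjustment for QALY
#' calculation. The result never exceeds any input; an empty comorbidity
#' list returns the base utility unchanged.
#'
#' @param base_utility Utility in `[0,1]` (vectorised).
#' @param comorbidity_utilities List (or vector) of utilities in `[0,1]`.
#' @return The product of all inputs.
#' @examples
#' combined_utility(0.8, list(0.9, 0.5))  # 0.36
#' @export
combined_utility <- function(base_utility, comorbidity_utilities = list()) {
  check01 <- function(u) {
    if (!all(is.finite(u)) || any(u < 0 | u > 1)) {
      stop("utilities must lie in [0,1]", call. = FALSE)
    }
    u
  }
  out <- check01(base_utility)
  for (u in comorbidity_utilities) out <- out * check01(u)
  out
}

lookup_or_stop <- function(values, nm, what) {
  v <- values[[nm]]
  if (is.null(v)) {
    stop(sprintf("missing %s entry '%s' in the parameter set", what, nm),
         call. = FALSE)
  }
  v
}

# Inpatient utility for a state: base inpatient utility adjusted
# multiplicatively for DVT and PE comorbidity.
inpatient_state_utility <- function(state, utilities) {
  u <- lookup_or_stop(utilities, "util_inpat", "utility")
  if (state %in% c("dnp", "dp")) {
    u <- combined_utility(u, list(lookup_or_stop(utilities, "util_dvt",
                                                 "utility")))
  }
  if (state == "dp") {
    u <- combined_utility(u, list(lookup_or_stop(utilities, "util_pe",
                                                 "utility")))
  }
  u
}

#' Time-weighted QALY of one pathway
#'
#' Inpatient-death pathways accrue `inpatient_death_day/365` years at the
#' inpatient utility (day-count convention for the day-15 rule). Survivors
#' accrue the inpatient month(s) at the inpatient-state utility, months up
#' to the event month at the post-discharge well utility, and the remaining
#' months at the outcome utility, with months weighted as 1/12 year.
#' Post-discharge death truncates accrual at the start of the event month.
#'
#' When the parameter set supplies whole-pathway QALY values (parameters
#' named `qaly_<state>_1_12m_<outcome>` / `qaly_<state>_inpat_death`), the
#' lookup returns those directly and this function passes them through.
#'
#' @param state Inpatient state: `"ndnp"` (no DVT, no PE), `"dnp"` (DVT
#'   without PE) or `"dp"` (DVT and PE).
#' @param outcome Post-discharge outcome (`"well"`, `"recstroke"`,
#'   `"recdvt"`, `"recpe"`, `"ankcon"`, `"death"`), or `NA` for inpatient
#'   death.
#' @param utilities Named list/vector of state utilities or whole-pathway
#'   QALY values.
#' @param timing A [timing_constants()] object.
#' @return QALY accrued on the pathway, in years (vectorised over the
#'   lookup values).
#' @export
pathway_qaly <- function(state, outcome = NA_character_, utilities,
                         timing = timing_constants()) {
  state <- match.arg(state, tree_states())
  if (!is.na(outcome)) outcome <- match.arg(outcome, tree_outcomes())
  utilities <- as.list(utilities)
  qn <- qaly_param_name(state, outcome)
  if (!is.null(utilities[[qn]])) return(utilities[[qn]])

  u_state <- inpatient_state_utility(state, utilities)
  if (is.na(outcome)) {
    return(timing$inpatient_death_day / 365 * u_state)
  }
  pre_months <- timing$postdischarge_event_month - 1L - timing$inpatient_months
  post_months <- timing$horizon_months - timing$postdischarge_event_month + 1L
  u_well <- lookup_or_stop(utilities, "util_postdis_well", "utility")
  q <- timing$inpatient_months / 12 * u_state + pre_months / 12 * u_well
  if (outcome == "death") return(q)
  u_out <- if (outcome == "well") u_well else {
    lookup_or_stop(utilities, paste0("util_postdis_", outcome), "utility")
  }
  q + post_months / 12 * u_out
}

outcome_cost_name <- function(outcome) {
  switch(outcome, well = NA_character_, death = NA_character_,
         recstroke = "cost_recstroke", recdvt = "cost_recdvt",
         recpe = "cost_recpe", ankcon = "cost_ankcon")
}

#' Cost accrued on one pathway
#'
#' Sums the device cost (comparator device cost plus the robotic sock's
#' price premium), the 1-month inpatient stay cost (halved for day-15
#' deaths), one-off event costs for each adverse event on the pathway, and
#' monthly post-discharge care costs for the months lived after discharge.
#'
#' @param state,outcome As in [pathway_qaly()].
#' @param costs Named list/vector of cost entries.
#' @param strategy A [strategy()] object, or a numeric price premium.
#' @param timing A [timing_constants()] object.
#' @return Cost in 2019 S$ (vectorised over the lookup values).
#' @export
pathway_cost <- function(state, outcome = NA_character_, costs, strategy,
                         timing = timing_constants()) {
  state <- match.arg(state, tree_states())
  if (!is.na(outcome)) outcome <- match.arg(outcome, tree_outcomes())
  costs <- as.list(costs)
  premium <- if (inherits(strategy, "strategy")) strategy$price_premium
             else as.numeric(strategy)
  total <- lookup_or_stop(costs, "cost_device", "cost") + premium
  if (state %in% c("dnp", "dp")) {
    total <- total + lookup_or_stop(costs, "cost_dvt", "cost")
  }
  if (state == "dp") total <- total + lookup_or_stop(costs, "cost_pe", "cost")
  stay <- lookup_or_stop(costs, "cost_inpat_stay", "cost")
  if (is.na(outcome)) {
    # Day-15 deaths accrue half the 1-month stay.
    return(total + stay * timing$inpatient_death_day /
             (30 * timing$inpatient_months))
  }
  total <- total + stay
  cn <- outcome_cost_name(outcome)
  if (!is.na(cn)) total <- total + lookup_or_stop(costs, cn, "cost")
  pre_months <- timing$postdischarge_event_month - 1L - timing$inpatient_months
  post_months <- timing$horizon_months - timing$postdischarge_event_month + 1L
  months_lived <- if (outcome == "death") pre_months else pre_months + post_months
  total + months_lived * lookup_or_stop(costs, "cost_postdis_monthly", "cost")
}

# Strategy-modified probabilities: for the sock arm, each flagged baseline
# probability is multiplied by the compliance-adjusted effective RR and
# clipped at 1; the comparator arm is the baseline (compliance 0).
modified_probability <- function(pv, prob_name, vacom, effects) {
  p <- lookup_or_stop(pv, prob_name, "probability")
  rr_name <- unname(effects[prob_name])
  if (length(rr_name) == 0 || is.na(rr_name) || !vacom) return(p)
  compliance <- lookup_or_stop(pv, "prob_compliance_vac", "probability")
  rr <- lookup_or_stop(pv, rr_name, "relative risk")
  arm_probability(p, effective_relative_risk(rr, compliance))
}

# Enumerate all 21 pathways for one arm. `pv` is a named list whose
# elements are scalars (base case) or equal-length vectors (PSA draws);
# everything below is vectorised. Returns parallel lists of labels,
# probabilities, costs and QALYs.
enumerate_pathways <- function(pv, premium, vacom, timing,
                               effects = default_effects()) {
  p_dvt <- modified_probability(pv, "prob_dvt", vacom, effects)
  p_pe <- lookup_or_stop(pv, "prob_pe_dvt", "probability")
  state_prob <- list(ndnp = 1 - p_dvt,
                     dnp = p_dvt * (1 - p_pe),
                     dp = p_dvt * p_pe)
  p_die_inpat <- lapply(stats::setNames(tree_states(), tree_states()),
                        function(s) {
    override <- paste0("prob_death_inpat_", s)
    if (!is.null(pv[[override]])) pv[[override]]
    else lookup_or_stop(pv, "prob_death_inpat", "probability")
  })

  out_prob <- list(
    recstroke = lookup_or_stop(pv, "prob_recstroke", "probability"),
    recdvt    = lookup_or_stop(pv, "prob_recdvt", "probability"),
    recpe     = lookup_or_stop(pv, "prob_recpe", "probability"),
    ankcon    = modified_probability(pv, "prob_ankcon", vacom, effects),
    death     = lookup_or_stop(pv, "prob_death_postdis", "probability")
  )
  residual <- 1 - Reduce(`+`, out_prob)
  if (any(residual < -1e-12)) {
    stop("invalid parameter set: post-discharge outcome probabilities sum to ",
         "more than 1 (residual well branch negative)", call. = FALSE)
  }
  out_prob <- c(list(well = pmax(residual, 0)), out_prob)

  labels <- character(0); probs <- list(); costs <- list(); qalys <- list()
  k <- 0L
  for (s in tree_states()) {
    # inpatient death (terminal)
    k <- k + 1L
    labels[k] <- pathway_label(s, NA_character_)
    probs[[k]] <- state_prob[[s]] * p_die_inpat[[s]]
    costs[[k]] <- pathway_cost(s, NA_character_, pv, premium, timing)
    qalys[[k]] <- pathway_qaly(s, NA_character_, pv, timing)
    surv <- state_prob[[s]] * (1 - p_die_inpat[[s]])
    for (o in tree_outcomes()) {
      k <- k + 1L
      labels[k] <- pathway_label(s, o)
      probs[[k]] <- surv * out_prob[[o]]
      costs[[k]] <- pathway_cost(s, o, pv, premium, timing)
      qalys[[k]] <- pathway_qaly(s, o, pv, timing)
    }
  }
  list(labels = labels, probs = probs, costs = costs, qalys = qalys)
}

# Probability-weighted expected cost and QALY, vectorised over draws.
expected_outcomes <- function(pv, premium, vacom, timing,
                              effects = default_effects()) {
  pw <- enumerate_pathways(pv, premium, vacom, timing, effects)
  cost <- 0; qaly <- 0
  for (k in seq_along(pw$labels)) {
    cost <- cost + pw$probs[[k]] * pw$costs[[k]]
    qaly <- qaly + pw$probs[[k]] * pw$qalys[[k]]
  }
  list(cost = cost, qaly = qaly)
}

resolve_arm <- function(strategy, scenario) {
  if (inherits(strategy, "strategy")) return(strategy)
  nm <- match.arg(strategy, c("VACOM", "IPC_manual"))
  strategy(nm, if (nm == "VACOM") scenario$price_premium else 0)
}

#' Evaluate one strategy by exact pathway enumeration
#'
#' Builds the full decision tree for a cohort and strategy — inpatient
#' chance nodes (DVT; PE given DVT; inpatient death), then one mutually
#' exclusive post-discharge outcome for survivors — applies the strategy's
#' compliance-adjusted relative risks to the flagged probabilities, and
#' returns the probability-weighted expected cost and QALY together with
#' all 21 pathway records.
#'
#' @param cohort `"is"` or `"ha"`.
#' @param strategy `"VACOM"`, `"IPC_manual"`, or a [strategy()] object.
#'   When given by name, the sock's price premium is taken from the
#'   scenario.
#' @param params A [parameter_table()].
#' @param scenario A [scenario_config()].
#' @return An object of class `strategy_result`: list with `strategy`,
#'   `cohort`, `expected_cost`, `expected_qaly` and a `pathways` data frame
#'   (`pathway`, `probability`, `cost`, `qaly`).
#' @export
build_and_evaluate <- function(cohort, strategy, params, scenario) {
  arm <- resolve_arm(strategy, scenario)
  tab <- apply_scenario(params, scenario)
  pv <- as.list(param_values(resolve_parameters(tab, cohort)))
  pw <- enumerate_pathways(pv, arm$price_premium, arm$name == "VACOM",
                           scenario$timing, scenario$effects)
  pathways <- data.frame(pathway = pw$labels,
                         probability = vapply(pw$probs, identity, 0),
                         cost = vapply(pw$costs, identity, 0),
                         qaly = vapply(pw$qalys, identity, 0),
                         stringsAsFactors = FALSE)
  ptot <- sum(pathways$probability)
  if (abs(ptot - 1) > 1e-12) {
    stop(sprintf("pathway probabilities sum to %.15f, not 1", ptot),
         call. = FALSE)
  }
  structure(list(strategy = arm, cohort = cohort,
                 expected_cost = sum(pathways$probability * pathways$cost),
                 expected_qaly = sum(pathways$probability * pathways$qaly),
                 pathways = pathways),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("strategy_result %s (cohort %s): E[cost] S$%.2f, E[QALY] %.5f over %d pathways\n",
              x$strategy$name, x$cohort, x$expected_cost, x$expected_qaly,
              nrow(x$pathways)))
  invisible(x)
}

#' Write pathway records to CSV
#'
#' One row per pathway: label, probability, cost, QALY.
#'
#' @param result A `strategy_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(result, path) {
  stopifnot(inherits(result, "strategy_result"))
  utils::write.csv(result$pathways, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Microsimulation cross-check of the tree evaluation
#'
#' Samples individual patients through the same chance nodes by Bernoulli
#' and categorical draws; the sample mean cost and QALY converge to the
#' exact enumeration of [build_and_evaluate()] as `n_patients` grows. Used
#' as an internal validation oracle for the enumeration.
#'
#' @inheritParams build_and_evaluate
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @return An object of class `microsim_result`: list with `expected_cost`,
#'   `expected_qaly`, their Monte-Carlo standard errors `se_cost`,
#'   `se_qaly`, and `n_patients`.
#' @export
microsimulate <- function(cohort, strategy, params, scenario, n_patients,
                          seed = 1L) {
  stopifnot(n_patients >= 1)
  arm <- resolve_arm(strategy, scenario)
  tab <- apply_scenario(params, scenario)
  pv <- as.list(param_values(resolve_parameters(tab, cohort)))
  vacom <- arm$name == "VACOM"
  timing <- scenario$timing
  effects <- scenario$effects

  p_dvt <- modified_probability(pv, "prob_dvt", vacom, effects)
  p_pe <- pv$prob_pe_dvt
  p_die <- vapply(tree_states(), function(s) {
    pv[[paste0("prob_death_inpat_", s)]] %||% pv$prob_death_inpat
  }, 0)
  out_p <- c(recstroke = pv$prob_recstroke, recdvt = pv$prob_recdvt,
             recpe = pv$prob_recpe,
             ankcon = modified_probability(pv, "prob_ankcon", vacom, effects),
             death = pv$prob_death_postdis)
  out_p <- c(well = max(0, 1 - sum(out_p)), out_p)
  if (1 - sum(out_p[-1]) < -1e-12) {
    stop("invalid parameter set: post-discharge probabilities exceed 1",
         call. = FALSE)
  }

  set.seed(as.integer(seed))
  n <- as.integer(n_patients)
  dvt <- stats::runif(n) < p_dvt
  pe <- dvt & (stats::runif(n) < p_pe)
  state_idx <- 1L + dvt + pe                    # 1 ndnp, 2 dnp, 3 dp
  died <- stats::runif(n) < p_die[state_idx]
  outcome_idx <- findInterval(stats::runif(n), cumsum(out_p),
                              left.open = TRUE) + 1L

  # Per-pathway deterministic cost/QALY, indexed 1..21 in enumeration order.
  pw <- enumerate_pathways(pv, arm$price_premium, vacom, timing, effects)
  cost_tab <- vapply(pw$costs, identity, 0)
  qaly_tab <- vapply(pw$qalys, identity, 0)
  # Pathway index: (state-1)*7 + 1 for inpatient death, +1+outcome otherwise.
  idx <- (state_idx - 1L) * 7L + ifelse(died, 1L, 1L + outcome_idx)
  cost_i <- cost_tab[idx]; qaly_i <- qaly_tab[idx]
  se <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else 0
  structure(list(expected_cost = mean(cost_i), expected_qaly = mean(qaly_i),
                 se_cost = se(cost_i), se_qaly = se(qaly_i),
                 n_patients = n, strategy = arm, cohort = cohort),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("microsim_result %s (n=%d): E[cost] S$%.2f (se %.2f), E[QALY] %.5f (se %.5f)\n",
              x$strategy$name, x$n_patients, x$expected_cost, x$se_cost,
              x$expected_qaly, x$se_qaly))
  invisible(x)
}
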