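# One-way deterministic sensitivity analysis with NMB tornado ranking, and
# price-premium threshold analysis.

# Incremental NMB (sock minus comparator) at base values, given a resolved
# value list; premium defaults to the scenario's.
incremental_nmb <- function(pv, scenario, threshold,
                            premium = scenario$price_premium) {
  vac <- expected_outcomes(pv, premium, TRUE, scenario$timing,
                           scenario$effects)
  ipc <- expected_outcomes(pv, 0, FALSE, scenario$timing, scenario$effects)
  threshold * (vac$qaly - ipc$qaly) - (vac$cost - ipc$cost)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each parameter in turn to its DSA low and high values (all others
#' at base), re-evaluates the incremental net monetary benefit at the
#' threshold, and reports the percent change relative to the base-case
#' NMB. Entries are ranked by span (the larger absolute percent change),
#' ties broken alphabetically. When the base NMB is exactly zero the
#' percent change is undefined and absolute NMB changes are reported
#' instead, flagged in the `metric` column.
#'
#' @inheritParams run_psa
#' @param threshold Willingness-to-pay, S$ per QALY (default the
#'   scenario's).
#' @return A data frame of class `tornado`, pre-sorted by descending
#'   `span`, with columns `parameter`, `base_value`, `dsa_low`, `dsa_high`,
#'   `nmb_at_low`, `nmb_at_high`, `pct_change_low`, `pct_change_high`,
#'   `span`, `metric`. The base NMB is stored in the `base_nmb` attribute.
#' @export
one_way_dsa <- function(cohort, params, scenario,
                        threshold = scenario$threshold) {
  tab <- apply_scenario(params, scenario)
  resolved <- resolve_parameters(tab, cohort)
  pv <- as.list(param_values(resolved))
  base_nmb <- incremental_nmb(pv, scenario, threshold)
  pct_mode <- base_nmb != 0

  rows <- lapply(seq_len(nrow(resolved)), function(i) {
    nm <- resolved$name[i]
    eval_at <- function(v) {
      pv2 <- pv; pv2[[nm]] <- v
      incremental_nmb(pv2, scenario, threshold)
    }
    lo <- eval_at(resolved$dsa_low[i])
    hi <- eval_at(resolved$dsa_high[i])
    if (pct_mode) {
      pl <- 100 * (lo - base_nmb) / abs(base_nmb)
      ph <- 100 * (hi - base_nmb) / abs(base_nmb)
    } else {
      pl <- lo - base_nmb; ph <- hi - base_nmb
    }
    data.frame(parameter = nm, base_value = resolved$base_value[i],
               dsa_low = resolved$dsa_low[i], dsa_high = resolved$dsa_high[i],
               nmb_at_low = lo, nmb_at_high = hi,
               pct_change_low = pl, pct_change_high = ph,
               span = max(abs(pl), abs(ph)),
               metric = if (pct_mode) "percent" else "absolute",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base_nmb
  class(out) <- c("tornado", "data.frame")
  out
}

#' Maximum chargeable price premium
#'
#' The premium at which the incremental net monetary benefit crosses zero,
#' i.e. the maximum additional per-patient price at which the sock remains
#' eligible for reimbursement at the threshold. Each extra S$1 of premium
#' reduces the incremental NMB by exactly S$1 per patient, so the closed
#' form is `premium0 + NMB_inc(premium0)`; the result is verified
#' internally against a bisection root to S$0.01 agreement. A negative
#' root (not reimbursable at any non-negative premium) is returned as 0
#' with the `not_reimbursable` attribute set (raw root in the `raw`
#' attribute).
#'
#' @inheritParams one_way_dsa
#' @return The maximum premium in S$ (numeric scalar) with attributes
#'   `not_reimbursable` (logical), `raw` (the unclipped root) and
#'   `bisection` (the independently bracketed root, `NA` when the root is
#'   negative).
#' @export
max_premium <- function(cohort, params, scenario,
                        threshold = scenario$threshold) {
  tab <- apply_scenario(params, scenario)
  pv <- as.list(param_values(resolve_parameters(tab, cohort)))
  premium0 <- scenario$price_premium
  nmb0 <- incremental_nmb(pv, scenario, threshold, premium = premium0)
  root <- premium0 + nmb0

  f <- function(p) incremental_nmb(pv, scenario, threshold, premium = p)
  bis <- NA_real_
  if (root >= 0 && root <= 1e6) {
    bis <- stats::uniroot(f, lower = 0, upper = 1e6, tol = 1e-4)$root
    if (abs(bis - root) > 0.01) {
      stop(sprintf("closed-form premium %.4f disagrees with bisection %.4f",
                   root, bis), call. = FALSE)
    }
  }
  out <- max(0, root)
  attr(out, "not_reimbursable") <- root < 0
  attr(out, "raw") <- root
  attr(out, "bisection") <- bis
  out
}

#' Threshold curve: maximum premium as a function of one parameter
#'
#' Sweeps one parameter over a grid (all others at base) and reports the
#' maximum chargeable premium at each value, mirroring the target product
#' profile analysis of premium versus the relative risk of DVT. For a
#' relative risk whose event raises cost and lowers QALY the curve is
#' non-increasing in the RR: a more effective sock supports a higher
#' premium.
#'
#' @inheritParams one_way_dsa
#' @param sweep_parameter Name of the parameter to sweep.
#' @param grid Numeric grid of values; must respect the parameter's role
#'   bounds.
#' @return A data frame with `value`, `max_premium`, `not_reimbursable`.
#' @export
threshold_curve <- function(cohort, params, scenario, sweep_parameter, grid,
                            threshold = scenario$threshold) {
  tab <- apply_scenario(params, scenario)
  resolved <- resolve_parameters(tab, cohort)
  if (!sweep_parameter %in% resolved$name) {
    stop("unknown sweep parameter: ", sweep_parameter, call. = FALSE)
  }
  role <- resolved$role[resolved$name == sweep_parameter]
  if (role %in% c("probability", "utility", "whole_pathway_qaly") &&
      any(grid < 0 | grid > 1)) {
    stop("grid values outside [0,1] for a ", role, " parameter", call. = FALSE)
  }
  if (role == "relative_risk" && any(grid <= 0)) {
    stop("grid values must be > 0 for a relative risk", call. = FALSE)
  }
  if (role == "cost" && any(grid < 0)) {
    stop("grid values must be >= 0 for a cost", call. = FALSE)
  }
  pv <- as.list(param_values(resolved))
  premium0 <- scenario$price_premium
  rows <- lapply(grid, function(v) {
    pv2 <- pv; pv2[[sweep_parameter]] <- v
    nmb0 <- incremental_nmb(pv2, scenario, threshold, premium = premium0)
    root <- premium0 + nmb0
    c(value = v, max_premium = max(0, root), not_reimbursable = root < 0)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$not_reimbursable <- as.logical(out$not_reimbursable)
  out
}
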