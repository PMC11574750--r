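# Incremental cost-utility statistics: ICER, NMB, dominance, CEAC, and the
# price-premium vs ICER curve.

#' Incremental cost-utility comparison of two strategies
#'
#' Computes the incremental cost and QALY of the intervention over the
#' comparator, the ICER (undefined when the QALY difference is zero), the
#' net monetary benefit `threshold * dQALY - dCost`, and a quadrant-aware
#' dominance class: `cost_saving_dominant` (no costlier and no less
#' effective, at least one strictly), `dominated` (the reverse), otherwise
#' `cost_effective`/`not_cost_effective` by the sign of the NMB (ties count
#' against the intervention). Using the NMB sign rather than a naive ICER
#' comparison keeps the southwest quadrant (cheaper but less effective)
#' classified correctly.
#'
#' @param intervention,comparator `strategy_result` objects (or any list
#'   with `expected_cost` and `expected_qaly`).
#' @param threshold Willingness-to-pay ceiling, S$ per QALY, `>= 0`.
#' @return An object of class `incremental_result`: list with `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` when undefined), `nmb`, `threshold`,
#'   `dominance`.
#' @export
incremental <- function(intervention, comparator, threshold = 75000) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  dc <- intervention$expected_cost - comparator$expected_cost
  de <- intervention$expected_qaly - comparator$expected_qaly
  icer <- if (de != 0) dc / de else NA_real_
  nmb <- threshold * de - dc
  dominance <- if ((dc <= 0 && de >= 0) && (dc < 0 || de > 0)) {
    "cost_saving_dominant"
  } else if ((dc >= 0 && de <= 0) && (dc > 0 || de < 0)) {
    "dominated"
  } else if (nmb > 0) "cost_effective" else "not_cost_effective"
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer, nmb = nmb,
                 threshold = threshold, dominance = dominance),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("incremental_result: dCost S$%.2f, dQALY %.6f, ICER %s, NMB S$%.2f at S$%g/QALY [%s]\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("S$%.0f/QALY", x$icer),
              x$nmb, x$threshold, x$dominance))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws on which
#' the intervention's incremental net monetary benefit is strictly
#' positive (ties count as not cost-effective).
#'
#' @param psa A `psa_samples` object from [run_psa()], or a list with
#'   numeric `delta_cost` and `delta_qaly` vectors.
#' @param thresholds Grid of thresholds, S$ per QALY.
#' @return A data frame with columns `threshold` and `prob_ce` in `[0,1]`.
#' @export
ceac <- function(psa, thresholds = seq(0, 150000, by = 5000)) {
  inc <- if (inherits(psa, "psa_samples")) psa_increments(psa) else psa
  dc <- inc$delta_cost; de <- inc$delta_qaly
  if (length(dc) < 2) stop("a CEAC needs at least 2 draws", call. = FALSE)
  prob <- vapply(thresholds, function(l) mean(l * de - dc > 0), 0)
  data.frame(threshold = thresholds, prob_ce = prob)
}

#' Price premium versus ICER curve
#'
#' Re-evaluates the sock arm at each premium on the grid, holding all other
#' parameters at base, and reports the ICER. Because each extra S$1 of
#' premium adds exactly S$1 to the incremental cost per patient and leaves
#' the QALY difference unchanged, the curve is affine with slope
#' `1/dQALY`; this is asserted to numerical tolerance.
#'
#' @inheritParams run_psa
#' @param premium_grid Numeric vector of premiums, S$.
#' @return A data frame with `premium`, `delta_cost`, `delta_qaly`, `icer`.
#'   When the QALY difference is zero the ICER column is `NA` and the
#'   `undefined` attribute is set.
#' @export
premium_icer_curve <- function(cohort, params, scenario, premium_grid) {
  stopifnot(length(premium_grid) >= 1, all(premium_grid >= 0))
  tab <- apply_scenario(params, scenario)
  pv <- as.list(param_values(resolve_parameters(tab, cohort)))
  ipc <- expected_outcomes(pv, 0, FALSE, scenario$timing, scenario$effects)
  rows <- lapply(premium_grid, function(p) {
    vac <- expected_outcomes(pv, p, TRUE, scenario$timing, scenario$effects)
    c(premium = p, delta_cost = vac$cost - ipc$cost,
      delta_qaly = vac$qaly - ipc$qaly)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (any(out$delta_qaly == 0)) {
    out$icer <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out$icer <- out$delta_cost / out$delta_qaly
  # affine check: ICER residuals from the analytic line premium/dE + c
  if (nrow(out) >= 2) {
    de <- out$delta_qaly[1]
    pred <- out$icer[1] + (out$premium - out$premium[1]) / de
    scale <- max(1, abs(out$icer))
    if (max(abs(out$icer - pred) / scale) > 1e-9) {
      stop("premium-ICER curve departed from the affine form 1/dQALY",
           call. = FALSE)
    }
  }
  out
}
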