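# Value-of-information analysis: EVPI over a threshold grid and
# per-parameter EVPPI by nested Monte Carlo and regression estimators.

psa_nmb <- function(psa, threshold) {
  cbind(VACOM = threshold * psa$qaly[, "VACOM"] - psa$cost[, "VACOM"],
        IPC_manual = threshold * psa$qaly[, "IPC_manual"] -
          psa$cost[, "IPC_manual"])
}

#' Expected value of perfect information
#'
#' The per-patient opportunity cost of deciding under current uncertainty:
#' for each threshold, the mean over PSA draws of the best strategy's net
#' monetary benefit minus the NMB of the strategy that is best on
#' average, `E[max_s NMB_s] - max_s E[NMB_s]`. Non-negative by
#' construction; tiny negative values from floating-point cancellation are
#' clipped to 0.
#'
#' @param psa A `psa_samples` object from [run_psa()].
#' @param thresholds Grid of willingness-to-pay values, S$ per QALY.
#' @return A data frame with `threshold` and `evpi` (S$ per patient).
#' @export
evpi <- function(psa, thresholds = seq(0, 150000, by = 5000)) {
  stopifnot(inherits(psa, "psa_samples"))
  if (nrow(psa$cost) < 2) stop("EVPI needs at least 2 draws", call. = FALSE)
  v <- vapply(thresholds, function(l) {
    nmb <- psa_nmb(psa, l)
    max(0, mean(pmax(nmb[, 1], nmb[, 2])) - max(colMeans(nmb)))
  }, 0)
  data.frame(threshold = thresholds, evpi = v)
}

#' EVPPI by nested Monte Carlo
#'
#' The expected value of removing uncertainty in one parameter (or a
#' subset): the outer loop draws the target parameter(s), the inner loop
#' draws all remaining parameters and averages each strategy's net
#' monetary benefit; EVPPI is the mean over outer draws of the best
#' inner-mean NMB, minus the overall best mean NMB. The Monte-Carlo
#' standard error is computed from the outer-loop variance. A fixed target
#' parameter has EVPPI exactly 0 and is returned without simulation.
#'
#' @inheritParams run_psa
#' @param target_parameter Character vector of parameter name(s) to treat
#'   as known.
#' @param n_outer,n_inner Outer and inner loop sizes, each `>= 2`.
#' @param seed Integer seed.
#' @param threshold Willingness-to-pay, S$ per QALY.
#' @param outer_draws Optional matrix (or vector, for one target) of outer
#'   draw values overriding the table's distribution — e.g. a discrete
#'   prior for validation against exhaustive enumeration.
#' @return A list with `evppi`, `mc_error`, `raw` (before clipping at 0),
#'   `n_outer`, `n_inner`, `estimator = "nested_mc"`.
#' @export
evppi_nested_mc <- function(cohort, params, scenario, target_parameter,
                            n_outer = 200, n_inner = 200,
                            seed = scenario$seed,
                            threshold = scenario$threshold,
                            outer_draws = NULL) {
  tab <- apply_scenario(params, scenario)
  resolved <- resolve_parameters(tab, cohort)
  if (!all(target_parameter %in% resolved$name)) {
    stop("unknown target parameter(s): ",
         paste(setdiff(target_parameter, resolved$name), collapse = ", "),
         call. = FALSE)
  }
  tgt <- resolved[resolved$name %in% target_parameter, , drop = FALSE]
  if (is.null(outer_draws) && all(tgt$dist_family == "fixed")) {
    return(list(evppi = 0, mc_error = 0, raw = 0, n_outer = 0L, n_inner = 0L,
                estimator = "nested_mc"))
  }
  if (n_outer < 2 || n_inner < 1) {
    stop("need n_outer >= 2 and n_inner >= 1", call. = FALSE)
  }
  others <- resolved[!resolved$name %in% target_parameter, , drop = FALSE]

  if (is.null(outer_draws)) {
    outer_draws <- sample_psa_draws(tgt, n_outer, seed)
  } else {
    if (is.vector(outer_draws)) {
      outer_draws <- matrix(outer_draws, ncol = 1,
                            dimnames = list(NULL, target_parameter[1]))
    }
    n_outer <- nrow(outer_draws)
  }
  inner_all <- if (nrow(others) > 0) {
    sample_psa_draws(others, n_outer * n_inner, seed + 1L)
  } else NULL

  arm_means <- matrix(NA_real_, n_outer, 2)
  for (j in seq_len(n_outer)) {
    if (is.null(inner_all)) {
      pv <- list()
      n_in <- 1L
    } else {
      idx <- ((j - 1L) * n_inner + 1L):(j * n_inner)
      pv <- lapply(seq_len(ncol(inner_all)), function(k) inner_all[idx, k])
      names(pv) <- colnames(inner_all)
      n_in <- n_inner
    }
    for (nm in colnames(outer_draws)) pv[[nm]] <- rep(outer_draws[j, nm], n_in)
    vac <- expected_outcomes(pv, scenario$price_premium, TRUE,
                             scenario$timing, scenario$effects)
    ipc <- expected_outcomes(pv, 0, FALSE, scenario$timing, scenario$effects)
    arm_means[j, ] <- c(mean(threshold * vac$qaly - vac$cost),
                        mean(threshold * ipc$qaly - ipc$cost))
  }
  best_given_theta <- pmax(arm_means[, 1], arm_means[, 2])
  raw <- mean(best_given_theta) - max(colMeans(arm_means))
  mc_error <- stats::sd(best_given_theta) / sqrt(n_outer)
  list(evppi = max(0, raw), mc_error = mc_error, raw = raw,
       n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
       estimator = "nested_mc")
}

#' EVPPI by single-loop regression on stored PSA draws
#'
#' Estimates the conditional mean of the incremental net monetary benefit
#' given the target parameter with a one-dimensional smoother, then takes
#' `E[max(0, fitted)] - max(0, E[dNMB])`. For two strategies this equals
#' the general best-strategy formulation. Targets with at most 10 unique
#' values use exact within-group means (so discrete toy priors are handled
#' without smoothing bias); continuous targets use a penalised thin-plate
#' spline fitted by [mgcv::gam()]. A constant target column returns 0.
#'
#' @param psa A `psa_samples` object with stored parameter draws.
#' @param target_parameter Name of one parameter column.
#' @param threshold Willingness-to-pay, S$ per QALY.
#' @param k Spline basis dimension for the continuous case.
#' @return A list with `evppi`, `raw`, `estimator = "regression"` and
#'   `method` metadata (smoother and basis dimension used).
#' @export
evppi_regression <- function(psa, target_parameter,
                             threshold = psa$scenario$threshold, k = 10) {
  stopifnot(inherits(psa, "psa_samples"))
  if (!target_parameter %in% colnames(psa$draws)) {
    stop("target column not present in PSA draws: ", target_parameter,
         call. = FALSE)
  }
  if (nrow(psa$draws) < 10) {
    stop("regression EVPPI needs a reasonably sized PSA (>= 10 draws; ",
         ">= 500 recommended)", call. = FALSE)
  }
  theta <- psa$draws[, target_parameter]
  nmb <- psa_nmb(psa, threshold)
  dnmb <- nmb[, "VACOM"] - nmb[, "IPC_manual"]
  n_unique <- length(unique(theta))
  if (n_unique == 1) {
    return(list(evppi = 0, raw = 0, estimator = "regression",
                method = "constant target"))
  }
  if (n_unique <= 10) {
    g <- stats::ave(dnmb, theta)
    method <- sprintf("exact group means over %d levels", n_unique)
  } else {
    kk <- min(k, n_unique - 1)
    fit <- mgcv::gam(dnmb ~ s(theta, k = kk))
    g <- stats::fitted(fit)
    method <- sprintf("mgcv::gam thin-plate spline, k = %d", kk)
  }
  raw <- mean(pmax(0, g)) - max(0, mean(dnmb))
  list(evppi = max(0, raw), raw = raw, estimator = "regression",
       method = method)
}

#' Scale a per-patient value of information to a population
#'
#' The effective population is an explicit user input; no default is
#' assumed.
#'
#' @param per_patient_voi Per-patient value, S$.
#' @param effective_population Number of patients the decision applies to,
#'   `>= 1`.
#' @return Population value, S$.
#' @export
scale_to_population <- function(per_patient_voi, effective_population) {
  if (missing(effective_population) || is.null(effective_population)) {
    stop("effective_population must be supplied explicitly", call. = FALSE)
  }
  if (any(effective_population < 1)) {
    stop("effective_population must be >= 1", call. = FALSE)
  }
  per_patient_voi * effective_population
}
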