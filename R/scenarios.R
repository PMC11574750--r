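# Timing constants and scenario configuration --------------------------------

#' Timing constants of the two-period model
#'
#' The model splits the 1-year horizon into a 1-month inpatient stay and a
#' post-discharge period (months 2-12). Patients who die as inpatients are
#' assumed to die on day 15 of the stay; post-discharge adverse events occur
#' at the start of month 7.
#'
#' @param horizon_months Analysis horizon in months (12).
#' @param inpatient_months Length of the inpatient stay in months (1).
#' @param inpatient_death_day Day of stay on which inpatient deaths occur (15).
#' @param postdischarge_event_month Calendar month (1-indexed) at whose start
#'   post-discharge complications occur (7).
#' @return An object of class `timing_constants`.
#' @export
timing_constants <- function(horizon_months = 12L, inpatient_months = 1L,
                             inpatient_death_day = 15L,
                             postdischarge_event_month = 7L) {
  t <- list(horizon_months = as.integer(horizon_months),
            inpatient_months = as.integer(inpatient_months),
            inpatient_death_day = as.integer(inpatient_death_day),
            postdischarge_event_month = as.integer(postdischarge_event_month))
  if (!(t$inpatient_months > 0 && t$inpatient_months < t$horizon_months)) {
    stop("need 0 < inpatient_months < horizon_months", call. = FALSE)
  }
  if (!(t$inpatient_death_day >= 1 &&
        t$inpatient_death_day <= 30L * t$inpatient_months)) {
    stop("inpatient_death_day must lie within the inpatient stay", call. = FALSE)
  }
  if (!(t$postdischarge_event_month > t$inpatient_months &&
        t$postdischarge_event_month <= t$horizon_months)) {
    stop("postdischarge_event_month must fall in the post-discharge period",
         call. = FALSE)
  }
  structure(t, class = "timing_constants")
}

#' Default mapping of strategy-modified probabilities to relative risks
#'
#' The robotic sock acts on two baseline probabilities: inpatient deep vein
#' thrombosis (via `rr_dvt_vac_ipc`) and post-discharge ankle contracture
#' (via `rr_ankcon_vac`). Additional entries can be supplied in a scenario's
#' `effects` field to flag other probabilities as strategy-modified.
#'
#' @return A named character vector: probability parameter -> RR parameter.
#' @export
default_effects <- function() {
  c(prob_dvt = "rr_dvt_vac_ipc", prob_ankcon = "rr_ankcon_vac")
}

#' Scenario configuration
#'
#' Bundles the pricing and effectiveness assumptions of one analysis
#' scenario: the per-patient price premium of the robotic sock over its
#' comparator, the relative risk of ankle contracture it is assumed to
#' achieve (0.3 in the optimistic scenario, 0.9 in the conservative one),
#' the willingness-to-pay ceiling threshold (S$75,000 per QALY), timing
#' constants, the random seed and the number of PSA draws.
#'
#' @param name Scenario label; `"optimistic"`, `"conservative"` or `"custom"`
#'   (a suffix such as `"conservative_300"` is allowed).
#' @param rr_ankcon_vac Relative risk of ankle contracture, sock vs
#'   comparator; must be 0.3 for optimistic and 0.9 for conservative
#'   scenarios. `NULL` leaves the parameter table's value untouched.
#' @param price_premium Extra per-patient price of the sock, 2019 S$.
#' @param cohort `"is"`, `"ha"` or `"both"`.
#' @param threshold Ceiling threshold, S$ per QALY.
#' @param timing A [timing_constants()] object.
#' @param seed Integer seed for stochastic stages.
#' @param n_psa Number of PSA draws.
#' @param discount_rate Annual discount rate; a no-op over the 1-year
#'   horizon and therefore 0 by default.
#' @param effects Named character vector mapping strategy-modified
#'   probability parameters to their RR parameters; see [default_effects()].
#' @param param_overrides Optional named list of additional base-value
#'   overrides applied by [apply_scenario()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom", rr_ankcon_vac = NULL,
                            price_premium = 150, cohort = "both",
                            threshold = 75000, timing = timing_constants(),
                            seed = 1L, n_psa = 5000L, discount_rate = 0,
                            effects = default_effects(),
                            param_overrides = list()) {
  stopifnot(inherits(timing, "timing_constants"))
  cohort <- match.arg(cohort, cohort_levels())
  if (price_premium < 0) stop("price_premium must be >= 0", call. = FALSE)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  base <- sub("_[0-9]+$", "", name)
  if (base == "optimistic" && !identical(as.numeric(rr_ankcon_vac), 0.3)) {
    stop("an optimistic scenario must carry rr_ankcon_vac = 0.3", call. = FALSE)
  }
  if (base == "conservative" && !identical(as.numeric(rr_ankcon_vac), 0.9)) {
    stop("a conservative scenario must carry rr_ankcon_vac = 0.9", call. = FALSE)
  }
  structure(list(name = name,
                 rr_ankcon_vac = if (is.null(rr_ankcon_vac)) NULL
                                 else as.numeric(rr_ankcon_vac),
                 price_premium = as.numeric(price_premium),
                 cohort = cohort, threshold = as.numeric(threshold),
                 timing = timing, seed = as.integer(seed),
                 n_psa = as.integer(n_psa),
                 discount_rate = as.numeric(discount_rate),
                 effects = effects, param_overrides = param_overrides),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config '%s': premium S$%g, threshold S$%g/QALY",
              x$name, x$price_premium, x$threshold))
  if (!is.null(x$rr_ankcon_vac)) {
    cat(sprintf(", rr_ankcon_vac %g", x$rr_ankcon_vac))
  }
  cat(sprintf(", cohort %s, n_psa %d, seed %d\n", x$cohort, x$n_psa, x$seed))
  invisible(x)
}

#' Built-in analysis scenarios
#'
#' The five scenarios analysed in the evaluation: optimistic (ankle
#' contracture RR 0.3) and conservative (RR 0.9), each at the revised
#' S$150 and original S$300 price premiums, plus the optimistic scenario at
#' a S$1,000 premium used in the value-of-information analysis. All use a
#' S$75,000/QALY ceiling threshold, a 12-month horizon with a 1-month
#' inpatient stay, inpatient deaths on day 15 and post-discharge events at
#' the start of month 7.
#'
#' @param seed Seed stored in each scenario.
#' @param n_psa PSA draws stored in each scenario.
#' @return A named list of [scenario_config()] objects.
#' @export
builtin_scenarios <- function(seed = 1L, n_psa = 5000L) {
  mk <- function(base, rr, premium) {
    scenario_config(name = sprintf("%s_%d", base, premium),
                    rr_ankcon_vac = rr, price_premium = premium,
                    seed = seed, n_psa = n_psa)
  }
  list(optimistic_150    = mk("optimistic", 0.3, 150L),
       optimistic_300    = mk("optimistic", 0.3, 300L),
       conservative_150  = mk("conservative", 0.9, 150L),
       conservative_300  = mk("conservative", 0.9, 300L),
       optimistic_1000   = mk("optimistic", 0.3, 1000L))
}

#' Read a scenario configuration from a YAML file
#'
#' @param path Path to a YAML document mirroring the [scenario_config()]
#'   fields (timing as a nested mapping).
#' @return A `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  timing <- if (is.null(y$timing)) timing_constants() else
    do.call(timing_constants, y$timing)
  effects <- if (is.null(y$effects)) default_effects() else
    unlist(y$effects)
  scenario_config(name = y$name %||% "custom",
                  rr_ankcon_vac = y$rr_ankcon_vac,
                  price_premium = y$price_premium %||% 150,
                  cohort = y$cohort %||% "both",
                  threshold = y$threshold %||% 75000,
                  timing = timing,
                  seed = y$seed %||% 1L,
                  n_psa = y$n_psa %||% 5000L,
                  discount_rate = y$discount_rate %||% 0,
                  effects = effects,
                  param_overrides = y$param_overrides %||% list())
}

#' Write a scenario configuration to YAML
#'
#' @param scenario A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  y <- unclass(scenario)
  y$timing <- unclass(y$timing)
  y$effects <- as.list(y$effects)
  yaml::write_yaml(y, path)
  invisible(path)
}
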