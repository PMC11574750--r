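# Synthetic parameter tables with the statistical structure the model
# assumes. Base values are placeholders drawn within literature-plausible
# ranges for post-stroke inpatients -- they are NOT the values of any
# specific published parameter set; a transcription template is shipped in
# inst/extdata for users holding real estimates.

#' Generator profile for synthetic parameter tables
#'
#' Defines the plausibility ranges from which base values are drawn, one
#' range per parameter, with cohort-specific ranges for the two mortality
#' probabilities (hemorrhagic stroke carries higher baseline mortality
#' than ischemic, and the generator enforces `ha >= is`). Complication
#' utilities are capped at the drawn post-discharge well utility, and the
#' sock's relative risks are at most 1 by default (non-harmful
#' intervention), overridable for stress tests.
#'
#' @param cohort `"both"` (generate rows for both cohorts), `"is"` or
#'   `"ha"`.
#' @param seed Integer seed; the generated table is deterministic in it.
#' @param ranges Optional named list overriding individual default ranges;
#'   each entry is `c(low, high)`. Cohort-specific entries use the names
#'   `prob_death_inpat_is`/`_ha` and `prob_death_postdis_is`/`_ha`.
#' @param se_frac Relative standard error given to every non-fixed
#'   parameter (default 0.2).
#' @return An object of class `generator_profile`.
#' @export
generator_profile <- function(cohort = "both", seed = 1L, ranges = list(),
                              se_frac = default_se_frac()) {
  cohort <- match.arg(cohort, cohort_levels())
  defaults <- list(
    prob_dvt              = c(0.06, 0.12),
    prob_pe_dvt           = c(0.15, 0.30),
    prob_death_inpat_is   = c(0.05, 0.10),
    prob_death_inpat_ha   = c(0.15, 0.30),
    prob_recstroke        = c(0.03, 0.08),
    prob_recdvt           = c(0.02, 0.05),
    prob_recpe            = c(0.005, 0.02),
    prob_ankcon           = c(0.15, 0.35),
    prob_death_postdis_is = c(0.05, 0.12),
    prob_death_postdis_ha = c(0.08, 0.18),
    prob_compliance_vac   = c(0.60, 0.90),
    rr_dvt_vac_ipc        = c(0.60, 0.95),
    rr_ankcon_vac         = c(0.30, 0.90),
    cost_device           = c(200, 500),
    cost_inpat_stay       = c(8000, 15000),
    cost_dvt              = c(1500, 4000),
    cost_pe               = c(5000, 12000),
    cost_recstroke        = c(10000, 20000),
    cost_recdvt           = c(1500, 4000),
    cost_recpe            = c(5000, 12000),
    cost_ankcon           = c(2000, 6000),
    cost_postdis_monthly  = c(150, 450),
    util_inpat            = c(0.45, 0.65),
    util_dvt              = c(0.90, 0.99),
    util_pe               = c(0.80, 0.95),
    util_postdis_well     = c(0.65, 0.80),
    util_postdis_recstroke = c(0.40, 0.55),
    util_postdis_recdvt   = c(0.55, 0.70),
    util_postdis_recpe    = c(0.50, 0.65),
    util_postdis_ankcon   = c(0.50, 0.65)
  )
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop("range for '", nm, "' must be a finite c(low, high) with low <= high",
           call. = FALSE)
    }
    defaults[[nm]] <- r
  }
  structure(list(cohort = cohort, seed = as.integer(seed),
                 ranges = defaults, se_frac = se_frac),
            class = "generator_profile")
}

param_role_of <- function(name) {
  if (startsWith(name, "prob_")) "probability"
  else if (startsWith(name, "rr_")) "relative_risk"
  else if (startsWith(name, "cost_")) "cost"
  else if (startsWith(name, "qaly_")) "whole_pathway_qaly"
  else if (startsWith(name, "util_")) "utility"
  else stop("cannot infer role for parameter: ", name, call. = FALSE)
}

# Standard error with beta-feasibility guard for [0,1] roles.
bounded_se <- function(role, base, se_frac) {
  se <- se_frac * base
  if (role %in% c("probability", "utility", "whole_pathway_qaly")) {
    cap <- 0.5 * sqrt(base * (1 - base))
    se <- min(se, cap)
  }
  se
}

#' Generate a synthetic parameter table
#'
#' Draws every base value uniformly within the profile's plausibility
#' range (deterministically under the profile's seed), enforces the
#' structural constraints (hemorrhagic mortality at least ischemic;
#' complication utilities at most the well utility), fits each
#' parameter's PSA distribution by [moments_to_dist()] with the profile's
#' relative standard error, and derives DSA bounds as the fitted
#' distribution's 2.5th/97.5th percentiles. The result always passes
#' [parameter_table()] validation and contains every parameter the
#' decision tree requires.
#'
#' @param profile A [generator_profile()].
#' @param qaly_mode `"whole_pathway"` (default): the table carries the 21
#'   whole-pathway QALY parameters (`qaly_ndnp_1_12m_well`, ...), computed
#'   from internally drawn state utilities via the decomposed accrual rule;
#'   `"decomposed"`: the table carries the state utilities instead.
#' @param timing Timing constants used to compute whole-pathway QALYs.
#' @return A validated `parameter_table`.
#' @export
generate_parameter_table <- function(profile = generator_profile(),
                                     qaly_mode = c("whole_pathway",
                                                   "decomposed"),
                                     timing = timing_constants()) {
  stopifnot(inherits(profile, "generator_profile"))
  qaly_mode <- match.arg(qaly_mode)
  set.seed(profile$seed)
  r <- profile$ranges
  draw <- function(nm) stats::runif(1, r[[nm]][1], r[[nm]][2])
  # Fixed draw order keeps tables deterministic under seed.
  vals <- list()
  for (nm in names(r)) vals[[nm]] <- draw(nm)
  # hemorrhagic mortality >= ischemic
  vals$prob_death_inpat_ha <- max(vals$prob_death_inpat_ha,
                                  vals$prob_death_inpat_is)
  vals$prob_death_postdis_ha <- max(vals$prob_death_postdis_ha,
                                    vals$prob_death_postdis_is)
  # complication utilities never exceed the well utility
  for (nm in c("util_postdis_recstroke", "util_postdis_recdvt",
               "util_postdis_recpe", "util_postdis_ankcon")) {
    vals[[nm]] <- min(vals[[nm]], vals$util_postdis_well)
  }

  util_names <- grep("^util_", names(vals), value = TRUE)
  rows <- list()
  add_row <- function(name, cohort, value, role = param_role_of(name)) {
    se <- bounded_se(role, value, profile$se_frac)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, cohort = cohort, role = role, base_value = value,
      se = se, stringsAsFactors = FALSE)
  }

  cohorts <- if (profile$cohort == "both") c("is", "ha") else profile$cohort
  for (nm in names(vals)) {
    if (nm %in% util_names && qaly_mode == "whole_pathway") next
    if (grepl("_(is|ha)$", nm)) {
      co <- sub("^.*_(is|ha)$", "\\1", nm)
      if (!co %in% cohorts) next
      add_row(sub("_(is|ha)$", "", nm), co, vals[[nm]])
    } else {
      add_row(nm, "both", vals[[nm]])
    }
  }

  if (qaly_mode == "whole_pathway") {
    utils_lookup <- vals[util_names]
    for (s in tree_states()) {
      add_row(qaly_param_name(s, NA_character_), "both",
              pathway_qaly(s, NA_character_, utils_lookup, timing))
      for (o in tree_outcomes()) {
        add_row(qaly_param_name(s, o), "both",
                pathway_qaly(s, o, utils_lookup, timing))
      }
    }
  }

  df <- do.call(rbind, rows)
  parameter_table(df)
}

#' Convert a decomposed-utility table to whole-pathway QALY form
#'
#' Replaces the state-utility rows of a table with the 21 whole-pathway
#' QALY parameters computed from them by the decomposed accrual rule, so
#' that evaluating either form of the table gives identical expected
#' values (round-trip property). Utility rows must apply to both cohorts.
#'
#' @param table A `parameter_table` in decomposed form.
#' @param timing Timing constants.
#' @param se_frac Relative standard error for the new QALY rows.
#' @return A `parameter_table` in whole-pathway form.
#' @export
as_whole_pathway <- function(table, timing = timing_constants(),
                             se_frac = default_se_frac()) {
  stopifnot(inherits(table, "parameter_table"))
  util_rows <- table[table$role == "utility", , drop = FALSE]
  if (nrow(util_rows) == 0) {
    stop("table has no utility rows to convert", call. = FALSE)
  }
  if (any(util_rows$cohort != "both")) {
    stop("as_whole_pathway requires cohort-shared ('both') utility rows",
         call. = FALSE)
  }
  utils_lookup <- stats::setNames(as.list(util_rows$base_value),
                                  util_rows$name)
  rows <- list()
  for (s in tree_states()) {
    for (o in c(NA_character_, tree_outcomes())) {
      q <- pathway_qaly(s, o, utils_lookup, timing)
      nm <- qaly_param_name(s, o)
      se <- bounded_se("whole_pathway_qaly", q, se_frac)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, cohort = "both", role = "whole_pathway_qaly",
        base_value = q, se = se, stringsAsFactors = FALSE)
    }
  }
  keep <- as.data.frame(table[table$role != "utility", , drop = FALSE])
  keep$se <- NA_real_
  new <- do.call(rbind, rows)
  new$dist_family <- NA_character_; new$dist_param1 <- NA_real_
  new$dist_param2 <- NA_real_; new$dsa_low <- NA_real_
  new$dsa_high <- NA_real_
  parameter_table(rbind(keep[c(param_table_columns(), "se")],
                        new[c(param_table_columns(), "se")]))
}

#' Packaged synthetic default parameter table
#'
#' Convenience wrapper: a complete synthetic table for both cohorts from
#' the default generator profile. Base values are synthetic placeholders
#' within literature-plausible ranges, not estimates from any particular
#' source.
#'
#' @param seed Generator seed.
#' @param qaly_mode Passed to [generate_parameter_table()].
#' @return A `parameter_table`.
#' @export
default_parameter_table <- function(seed = 20190L,
                                    qaly_mode = "whole_pathway") {
  generate_parameter_table(generator_profile(seed = seed),
                           qaly_mode = qaly_mode)
}
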