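# Canonical vocabularies for the parameter table ------------------------------

param_roles <- function() {
  c("probability", "relative_risk", "cost", "utility", "whole_pathway_qaly")
}

dist_families <- function() c("beta", "gamma", "lognormal", "fixed")

cohort_levels <- function() c("is", "ha", "both")

# Families admissible for each role; bounded-by-construction sampling depends
# on this mapping (beta for [0,1] roles, gamma for costs, lognormal for RRs).
role_family_map <- function() {
  list(
    probability        = c("beta", "fixed"),
    utility            = c("beta", "fixed"),
    whole_pathway_qaly = c("beta", "fixed"),
    cost               = c("gamma", "fixed"),
    relative_risk      = c("lognormal", "fixed")
  )
}

# Default relative standard error used when a table row carries no
# uncertainty information: 20% of the base value.
default_se_frac <- function() 0.2

param_table_columns <- function() {
  c("name", "cohort", "role", "base_value", "dist_family",
    "dist_param1", "dist_param2", "dsa_low", "dsa_high")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated parameter table
#'
#' A parameter table holds one row per model parameter: its mnemonic name
#' (e.g. `prob_dvt`, `rr_ankcon_vac`, `qaly_ndnp_1_12m_well`), the cohort it
#' applies to (`"is"` ischemic, `"ha"` hemorrhagic, or `"both"`), its role,
#' deterministic base value, probabilistic-sensitivity-analysis distribution
#' (`beta`/`gamma`/`lognormal`/`fixed` with family-specific parameters), and
#' the low/high values used in one-way deterministic sensitivity analysis.
#'
#' Rows with missing distribution information are completed by
#' [moments_to_dist()] using a standard error of 20% of the base value;
#' missing DSA bounds default to the 2.5th/97.5th percentiles of the fitted
#' distribution (or the base value itself for `fixed` rows).
#'
#' @param df A data frame with columns `name`, `cohort`, `role`, `base_value`
#'   and optionally `dist_family`, `dist_param1`, `dist_param2`, `se`,
#'   `dsa_low`, `dsa_high`.
#' @return An object of class `parameter_table` (a data frame).
#' @seealso [read_parameter_table()], [sample_psa_draws()]
#' @export
parameter_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("name", "cohort", "role", "base_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$name <- as.character(df$name)
  df$cohort <- tolower(as.character(df$cohort))
  df$role <- as.character(df$role)
  df$base_value <- as.numeric(df$base_value)
  se <- if ("se" %in% names(df)) as.numeric(df$se) else rep(NA_real_, nrow(df))
  for (col in c("dist_family")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!nzchar(trimws(as.character(df[[col]])))] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("dist_param1", "dist_param2", "dsa_low", "dsa_high")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }

  # Fill distributions and DSA ranges row-wise where absent. Base values on
  # or outside the role's open interval (0, 1 for bounded roles) get a
  # 'fixed' family; truly invalid values are caught by validation below.
  for (i in seq_len(nrow(df))) {
    if (is.na(df$dist_family[i])) {
      b <- df$base_value[i]
      role <- if (df$role[i] %in% param_roles()) df$role[i] else NA
      bounded <- isTRUE(role %in% c("probability", "utility",
                                    "whole_pathway_qaly"))
      fittable <- is.finite(b) && !is.na(role) &&
        if (bounded) (b > 0 && b < 1) else b > 0
      se_i <- se[i]
      if (is.na(se_i) && fittable) {
        se_i <- default_se_frac() * b
        if (bounded) se_i <- min(se_i, 0.5 * sqrt(b * (1 - b)))
      }
      if (!fittable || se_i <= 0) {
        df$dist_family[i] <- "fixed"
        df$dist_param1[i] <- NA_real_
        df$dist_param2[i] <- NA_real_
      } else {
        fit <- moments_to_dist(role, b, se_i)
        df$dist_family[i] <- fit$dist_family
        df$dist_param1[i] <- fit$dist_param1
        df$dist_param2[i] <- fit$dist_param2
      }
    }
    if (is.na(df$dsa_low[i]) || is.na(df$dsa_high[i])) {
      q <- dist_quantiles(df$dist_family[i], df$dist_param1[i],
                          df$dist_param2[i], c(0.025, 0.975),
                          base = df$base_value[i])
      df$dsa_low[i] <- min(q[1], df$base_value[i])
      df$dsa_high[i] <- max(q[2], df$base_value[i])
    }
  }

  df <- df[param_table_columns()]
  rownames(df) <- NULL
  errors <- validate_parameter_rows(df)
  if (length(errors) > 0) {
    stop("invalid parameter table:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  class(df) <- c("parameter_table", "data.frame")
  df
}

# Per-row validation; returns a character vector of messages naming the row,
# field and violated rule (empty when valid).
validate_parameter_rows <- function(df) {
  errors <- character(0)
  add <- function(row, field, rule) {
    errors[[length(errors) + 1L]] <<-
      sprintf("row %d (%s): field '%s' violates: %s", row, df$name[row],
              field, rule)
  }
  fam_map <- role_family_map()
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$name[i])) add(i, "name", "must be non-empty")
    if (!df$cohort[i] %in% cohort_levels()) {
      add(i, "cohort", "must be one of is/ha/both")
    }
    if (!df$role[i] %in% param_roles()) {
      add(i, "role", paste("must be one of", paste(param_roles(), collapse = "/")))
      next
    }
    b <- df$base_value[i]
    if (!is.finite(b)) { add(i, "base_value", "must be finite"); next }
    role <- df$role[i]
    if (role %in% c("probability", "utility", "whole_pathway_qaly") &&
        (b < 0 || b > 1)) {
      add(i, "base_value", "must lie in [0,1] for this role")
    }
    if (role == "cost" && b < 0) add(i, "base_value", "must be >= 0 for costs")
    if (role == "relative_risk" && b <= 0) {
      add(i, "base_value", "must be > 0 for relative risks")
    }
    fam <- df$dist_family[i]
    if (!fam %in% dist_families()) {
      add(i, "dist_family", paste("must be one of",
                                  paste(dist_families(), collapse = "/")))
    } else if (!fam %in% fam_map[[role]]) {
      add(i, "dist_family",
          sprintf("'%s' not admissible for role '%s' (allowed: %s)",
                  fam, role, paste(fam_map[[role]], collapse = "/")))
    } else if (fam != "fixed") {
      p1 <- df$dist_param1[i]; p2 <- df$dist_param2[i]
      if (fam %in% c("beta", "gamma")) {
        if (!is.finite(p1) || p1 <= 0 || !is.finite(p2) || p2 <= 0) {
          add(i, "dist_param1/2", "beta/gamma parameters must be positive")
        }
      } else if (fam == "lognormal") {
        if (!is.finite(p1) || !is.finite(p2) || p2 <= 0) {
          add(i, "dist_param1/2", "lognormal needs finite meanlog and sdlog > 0")
        }
      }
    }
    if (is.finite(df$dsa_low[i]) && is.finite(df$dsa_high[i])) {
      if (!(df$dsa_low[i] <= b && b <= df$dsa_high[i])) {
        add(i, "dsa_low/dsa_high", "must bracket base_value")
      }
    } else {
      add(i, "dsa_low/dsa_high", "must be finite")
    }
  }
  key <- paste(df$name, df$cohort, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    for (d in unique(dup)) {
      parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
      errors[[length(errors) + 1L]] <-
        sprintf("name '%s' duplicated within cohort '%s'", parts[1], parts[2])
    }
  }
  errors
}

#' Read a parameter table from a CSV file
#'
#' The file is comma-separated with a header row, UTF-8 encoded, `.` decimal
#' separator; lines starting with `#` are treated as comments. Columns `name`,
#' `cohort`, `role`, `base_value` are required; distribution columns, an `se`
#' column, and `dsa_low`/`dsa_high` are optional and completed as described in
#' [parameter_table()].
#'
#' @param path Path to a CSV file.
#' @return A validated `parameter_table`.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  parameter_table(df)
}

#' Write a parameter table to CSV
#'
#' Inverse of [read_parameter_table()]: `read_parameter_table(write_parameter_table(x, f))`
#' reproduces `x` on valid tables.
#'
#' @param table A `parameter_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  stopifnot(inherits(table, "parameter_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.parameter_table <- function(x, ...) {
  cat(sprintf("parameter_table: %d parameters (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$role)[unique(x$role)],
                            unique(x$role)), collapse = ", ")))
  NextMethod()
  invisible(x)
}

#' Resolve a parameter table for one cohort
#'
#' Keeps rows whose cohort is `"both"` or the requested cohort; a
#' cohort-specific row overrides a `"both"` row of the same name. The result
#' has unique names and can be sampled or turned into a value list.
#'
#' @param table A `parameter_table`.
#' @param cohort `"is"` (ischemic) or `"ha"` (hemorrhagic).
#' @return A `parameter_table` with unique names, carrying a `cohort` attribute.
#' @export
resolve_parameters <- function(table, cohort) {
  stopifnot(inherits(table, "parameter_table"))
  cohort <- match.arg(cohort, c("is", "ha"))
  keep <- table[table$cohort %in% c("both", cohort), , drop = FALSE]
  specific <- keep$name[keep$cohort == cohort]
  keep <- keep[!(keep$cohort == "both" & keep$name %in% specific), , drop = FALSE]
  keep <- keep[order(keep$name), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("parameter_table", "data.frame")
  attr(keep, "cohort") <- cohort
  keep
}

#' Extract base values from a resolved parameter table
#'
#' @param table A resolved `parameter_table` (unique names).
#' @return A named numeric vector of base values.
#' @export
param_values <- function(table) {
  stopifnot(inherits(table, "parameter_table"))
  if (anyDuplicated(table$name)) {
    stop("parameter names are not unique; resolve_parameters() first",
         call. = FALSE)
  }
  stats::setNames(table$base_value, table$name)
}

# Quantiles of a fitted distribution, used for default DSA ranges.
dist_quantiles <- function(family, p1, p2, probs, base) {
  switch(family,
    fixed     = rep(base, length(probs)),
    beta      = stats::qbeta(probs, p1, p2),
    gamma     = stats::qgamma(probs, shape = p1, rate = p2),
    lognormal = stats::qlnorm(probs, meanlog = p1, sdlog = p2),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# Analytic mean of a fitted distribution (used in tests and refitting).
dist_mean <- function(family, p1, p2, base) {
  switch(family,
    fixed     = base,
    beta      = p1 / (p1 + p2),
    gamma     = p1 / p2,
    lognormal = exp(p1 + p2^2 / 2),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

#' Fit an uncertainty distribution from a mean and standard error
#'
#' Method-of-moments fits by parameter role: beta for probabilities,
#' utilities and whole-pathway QALYs; gamma (shape/rate) for costs;
#' lognormal (meanlog/sdlog of the natural scale moments) for relative
#' risks. The fitted distribution reproduces the requested mean exactly
#' (to numerical precision).
#'
#' @param role One of `"probability"`, `"utility"`, `"whole_pathway_qaly"`,
#'   `"cost"`, `"relative_risk"`.
#' @param mean Target mean, within the role's bounds.
#' @param se Target standard error, `> 0`.
#' @return A list with `dist_family`, `dist_param1`, `dist_param2`.
#' @examples
#' moments_to_dist("cost", 1000, 200)   # gamma shape 25, rate 0.025
#' @export
moments_to_dist <- function(role, mean, se) {
  role <- match.arg(role, param_roles())
  if (role == "relative_risk" && !(is.finite(mean) && mean > 0)) {
    stop("relative-risk mean must be > 0", call. = FALSE)
  }
  if (!is.finite(mean) || !is.finite(se) || se <= 0) {
    stop("mean must be finite and se > 0", call. = FALSE)
  }
  if (role %in% c("probability", "utility", "whole_pathway_qaly")) {
    if (mean <= 0 || mean >= 1) {
      stop("beta fit needs mean strictly inside (0,1)", call. = FALSE)
    }
    v <- se^2
    if (v >= mean * (1 - mean)) {
      stop(sprintf(
        "infeasible moments for beta: se^2 = %.6g must be < mean*(1-mean) = %.6g",
        v, mean * (1 - mean)), call. = FALSE)
    }
    nu <- mean * (1 - mean) / v - 1
    list(dist_family = "beta", dist_param1 = mean * nu,
         dist_param2 = (1 - mean) * nu)
  } else if (role == "cost") {
    if (mean <= 0) stop("gamma fit needs mean > 0", call. = FALSE)
    list(dist_family = "gamma", dist_param1 = (mean / se)^2,
         dist_param2 = mean / se^2)
  } else {
    sigma2 <- log(1 + se^2 / mean^2)
    list(dist_family = "lognormal", dist_param1 = log(mean) - sigma2 / 2,
         dist_param2 = sqrt(sigma2))
  }
}

#' Draw probabilistic-sensitivity-analysis parameter samples
#'
#' Samples each parameter from its fitted distribution: beta for
#' probability/utility/QALY roles, gamma for costs, lognormal for relative
#' risks, a constant column for `fixed` rows. Draws respect role bounds by
#' construction (no post-hoc clipping). Columns are generated in
#' alphabetical parameter order from a single stream seeded once, so the
#' result is reproducible under `seed` and invariant to table row order.
#'
#' @param table A `parameter_table`; resolved via [resolve_parameters()] if
#'   `cohort` is supplied, otherwise it must already have unique names.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param cohort Optional cohort to resolve for.
#' @return An `n` x `p` numeric matrix with parameter names as column names.
#' @export
sample_psa_draws <- function(table, n, seed, cohort = NULL) {
  stopifnot(inherits(table, "parameter_table"), n >= 1)
  if (!is.null(cohort)) table <- resolve_parameters(table, cohort)
  if (anyDuplicated(table$name)) {
    stop("parameter names are not unique; supply `cohort` or resolve first",
         call. = FALSE)
  }
  ord <- order(table$name)
  tab <- table[ord, , drop = FALSE]
  out <- matrix(NA_real_, nrow = n, ncol = nrow(tab),
                dimnames = list(NULL, tab$name))
  set.seed(as.integer(seed))
  for (j in seq_len(nrow(tab))) {
    out[, j] <- switch(tab$dist_family[j],
      fixed     = rep(tab$base_value[j], n),
      beta      = stats::rbeta(n, tab$dist_param1[j], tab$dist_param2[j]),
      gamma     = stats::rgamma(n, shape = tab$dist_param1[j],
                                rate = tab$dist_param2[j]),
      lognormal = stats::rlnorm(n, meanlog = tab$dist_param1[j],
                                sdlog = tab$dist_param2[j])
    )
  }
  out
}

#' Apply a scenario's parameter overrides to a table
#'
#' A named scenario (optimistic/conservative) fixes the relative risk of
#' ankle contracture under the robotic sock. The override resets the row's
#' base value and refits its PSA distribution and DSA range using the
#' default 20%-of-base standard-error rule, so the parameter stays part of
#' the probabilistic and deterministic sensitivity analyses.
#'
#' @param table A `parameter_table`.
#' @param scenario A `scenario_config`.
#' @return The modified `parameter_table`.
#' @export
apply_scenario <- function(table, scenario) {
  stopifnot(inherits(table, "parameter_table"),
            inherits(scenario, "scenario_config"))
  overrides <- scenario$param_overrides %||% list()
  if (!is.null(scenario$rr_ankcon_vac)) {
    overrides[["rr_ankcon_vac"]] <- scenario$rr_ankcon_vac
  }
  if (length(overrides) == 0) return(table)
  df <- as.data.frame(table)
  for (nm in names(overrides)) {
    idx <- which(df$name == nm)
    if (length(idx) == 0) {
      stop("scenario overrides unknown parameter: ", nm, call. = FALSE)
    }
    val <- as.numeric(overrides[[nm]])
    for (i in idx) {
      df$base_value[i] <- val
      se <- default_se_frac() * abs(val)
      if (se > 0) {
        fit <- moments_to_dist(df$role[i], val, se)
        df$dist_family[i] <- fit$dist_family
        df$dist_param1[i] <- fit$dist_param1
        df$dist_param2[i] <- fit$dist_param2
      } else {
        df$dist_family[i] <- "fixed"
        df$dist_param1[i] <- NA_real_
        df$dist_param2[i] <- NA_real_
      }
      q <- dist_quantiles(df$dist_family[i], df$dist_param1[i],
                          df$dist_param2[i], c(0.025, 0.975), base = val)
      df$dsa_low[i] <- min(q[1], val)
      df$dsa_high[i] <- max(q[2], val)
    }
  }
  out <- parameter_table(df)
  attr(out, "cohort") <- attr(table, "cohort")
  out
}
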