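# Run orchestration: execute requested stages for one or both cohorts,
# write tabular outputs and a YAML manifest. Results go only to files;
# progress messages go to standard error.

write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full evaluation pipeline
#'
#' Executes the requested stage(s) for each cohort and writes tabular
#' outputs plus a YAML manifest to `out_dir`:
#' \describe{
#'   \item{cea}{Base-case table (expected cost/QALY per strategy, dCost,
#'     dQALY, ICER, NMB, dominance) and per-strategy pathway files.}
#'   \item{psa}{Cost-effectiveness acceptability curve
#'     (`ceac_<cohort>_<scenario>.csv`).}
#'   \item{dsa}{Full tornado table and the top-15 view.}
#'   \item{threshold}{Maximum chargeable premium, the premium-vs-ICER
#'     curve, and premium threshold curves over the two effectiveness
#'     relative risks.}
#'   \item{voi}{Per-patient EVPI over the threshold grid and per-parameter
#'     regression EVPPI at the scenario threshold.}
#' }
#' All stochastic stages derive from `seed`, so re-running with the same
#' inputs reproduces every output byte-identically. On error, files
#' already written by the failed run are removed.
#'
#' @param command One of `"all"`, `"cea"`, `"psa"`, `"dsa"`,
#'   `"threshold"`, `"voi"`.
#' @param scenario A [scenario_config()].
#' @param params A [parameter_table()]; `NULL` uses the packaged synthetic
#'   default table ([default_parameter_table()]).
#' @param cohorts Character vector of cohorts (`"is"`, `"ha"`).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default the scenario's).
#' @param n_psa PSA draws (default the scenario's).
#' @param top_n Parameters shown in the tornado top view.
#' @param verbose Emit stage progress to standard error.
#' @return Invisibly, a list with `files` (paths written) and `manifest`.
#' @export
run_analysis <- function(command = c("all", "cea", "psa", "dsa", "threshold",
                                     "voi"),
                         scenario = builtin_scenarios()$conservative_150,
                         params = NULL,
                         cohorts = c("is", "ha"),
                         out_dir = "vacomhta_results",
                         seed = scenario$seed, n_psa = scenario$n_psa,
                         top_n = 15, verbose = TRUE) {
  command <- match.arg(command)
  cohorts <- match.arg(cohorts, c("is", "ha"), several.ok = TRUE)
  param_source <- if (is.null(params)) "synthetic default (seed 20190)"
                  else "user-supplied"
  if (is.null(params)) params <- default_parameter_table()
  stopifnot(inherits(params, "parameter_table"),
            inherits(scenario, "scenario_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_result_csv(df, path)
    files <<- c(files, path)
    path
  }
  stages <- if (command == "all") c("cea", "psa", "dsa", "threshold", "voi")
            else command

  run_one <- function() {
    for (cohort in cohorts) {
      tag <- sprintf("%s_%s", cohort, scenario$name)
      psa <- NULL
      if (any(c("psa", "voi") %in% stages)) {
        stage_log(verbose, "[%s] PSA: %d draws", tag, n_psa)
        psa <- run_psa(cohort, params, scenario, n = n_psa, seed = seed)
      }
      if ("cea" %in% stages) {
        stage_log(verbose, "[%s] base-case cost-utility analysis", tag)
        vac <- build_and_evaluate(cohort, "VACOM", params, scenario)
        ipc <- build_and_evaluate(cohort, "IPC_manual", params, scenario)
        inc <- incremental(vac, ipc, scenario$threshold)
        emit(data.frame(cohort = cohort, scenario = scenario$name,
                        price_premium = scenario$price_premium,
                        cost_vacom = vac$expected_cost,
                        qaly_vacom = vac$expected_qaly,
                        cost_ipc = ipc$expected_cost,
                        qaly_ipc = ipc$expected_qaly,
                        delta_cost = inc$delta_cost,
                        delta_qaly = inc$delta_qaly,
                        icer = inc$icer, nmb = inc$nmb,
                        dominance = inc$dominance),
             sprintf("basecase_%s.csv", tag))
        emit(vac$pathways, sprintf("pathways_vacom_%s.csv", tag))
        emit(ipc$pathways, sprintf("pathways_ipc_%s.csv", tag))
      }
      if ("psa" %in% stages) {
        emit(ceac(psa), sprintf("ceac_%s.csv", tag))
      }
      if ("dsa" %in% stages) {
        stage_log(verbose, "[%s] one-way DSA tornado", tag)
        tor <- one_way_dsa(cohort, params, scenario)
        emit(as.data.frame(tor), sprintf("tornado_%s.csv", tag))
        emit(utils::head(as.data.frame(tor), top_n),
             sprintf("tornado_top%d_%s.csv", top_n, tag))
      }
      if ("threshold" %in% stages) {
        stage_log(verbose, "[%s] threshold analysis", tag)
        mp <- max_premium(cohort, params, scenario)
        emit(data.frame(cohort = cohort, scenario = scenario$name,
                        max_premium = as.numeric(mp),
                        not_reimbursable = attr(mp, "not_reimbursable")),
             sprintf("max_premium_%s.csv", tag))
        emit(premium_icer_curve(cohort, params, scenario,
                                seq(0, 1000, by = 50)),
             sprintf("premium_icer_%s.csv", tag))
        for (rr in c("rr_dvt_vac_ipc", "rr_ankcon_vac")) {
          emit(threshold_curve(cohort, params, scenario, rr,
                               seq(0.1, 1.0, by = 0.1)),
               sprintf("threshold_%s_%s.csv", rr, tag))
        }
      }
      if ("voi" %in% stages) {
        stage_log(verbose, "[%s] value-of-information analysis", tag)
        emit(evpi(psa), sprintf("evpi_%s.csv", tag))
        resolved <- resolve_parameters(apply_scenario(params, scenario),
                                       cohort)
        live <- resolved$name[resolved$dist_family != "fixed"]
        ev <- vapply(live, function(nm) {
          evppi_regression(psa, nm, scenario$threshold)$evppi
        }, 0)
        emit(data.frame(parameter = live, evppi = unname(ev),
                        mc_error = NA_real_, estimator = "regression"),
             sprintf("evppi_%s.csv", tag))
      }
    }
  }
  ok <- FALSE
  tryCatch({ run_one(); ok <- TRUE },
           finally = if (!ok) unlink(files))

  manifest <- list(scenario = scenario$name, cohorts = as.list(cohorts),
                   command = command, parameter_source = param_source,
                   n_psa = as.integer(n_psa), seed = as.integer(seed),
                   threshold = scenario$threshold,
                   price_premium = scenario$price_premium,
                   package_version = as.character(utils::packageVersion("vacomhta")),
                   out_dir = out_dir,
                   outputs = as.list(basename(files)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(files = files, manifest = manifest,
                 manifest_path = manifest_path))
}
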