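# Pipeline orchestration: survival data acquisition (simulated or from CSV),
# six-family fitting with AIC/BIC selection, indirect-comparison
# cross-check, base-case and scenario runs, deterministic and probabilistic
# sensitivity analysis, and CSV export of every stage's outputs.

#' Run the full cost-effectiveness pipeline
#'
#' Executes the requested stages in dependency order:
#'
#' 1. **data** (always): simulate pseudo-IPD per endpoint from the
#'    configuration's calibration (or read the configured IPD CSVs).
#' 2. **fit** (always): fit all six parametric families to each endpoint
#'    and select the best by AIC/BIC.
#' 3. **nma** (always, cheap): anchored Bucher and Bayesian indirect
#'    comparison from the configured trial effects, as a consistency check
#'    on the configured hazard ratios (the pipeline itself uses the
#'    configured HRs).
#' 4. **base**: two-arm trace and incremental comparison.
#' 5. **scenario**: same with the reduced bevacizumab dose
#'    (`scenario_bevacizumab_mg_per_kg`, default 7.5 mg/kg); efficacy
#'    inputs are untouched, so QALYs are identical to base by construction.
#' 6. **dsa**: one-way sensitivity analysis over all parameters.
#' 7. **psa**: probabilistic sensitivity analysis.
#'
#' All randomness (data simulation, Bayesian draws, PSA) derives from
#' `seed`. A run log of the assumptions in force (body weight, horizon,
#' treatment cap, follow-up schedule) is included in the bundle and echoed
#' via `message()`.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param stages subset of `c("base", "scenario", "dsa", "psa")`.
#' @param seed integer master seed; defaults to the configured seed.
#' @param psa_iterations Monte Carlo iterations for the PSA stage.
#' @param outdir optional directory; when given, every stage's tables are
#'   written there as CSV.
#' @param quiet suppress the run-log messages.
#' @return A result bundle (list) with elements `data`, `fits`,
#'   `selected`, `nma`, and the requested `base`, `scenario`, `dsa`, `psa`,
#'   plus `log` (character vector of echoed assumptions).
#' @export
run_pipeline <- function(config,
                         stages = c("base", "scenario", "dsa", "psa"),
                         seed = config$settings$seed,
                         psa_iterations = config$settings$psa_iterations %||% 5000L,
                         outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  log <- c(
    sprintf("seed: %d", seed),
    sprintf("body weight: %g kg (whole-vial wastage assumed)",
            config$settings$body_weight_kg),
    sprintf("horizon: %d cycles of %g weeks",
            config$settings$horizon_cycles, config$settings$cycle_weeks),
    sprintf("treatment cap, %s: %s cycles", config$strategies$intervention,
            format(.cap_cycles(
              config$treatment_cap_cycles[[config$strategies$intervention]]))),
    sprintf("adverse-event window: %.2f cycles",
            config$settings$ae_window_cycles),
    "follow-up panel: full panel per cycle for alive patients",
    "administration bundle: all components for the IV arm, diagnosis only for the oral arm"
  )
  if (!quiet) for (line in log) message(line)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  out_path <- function(name) if (is.null(outdir)) NULL
                             else file.path(outdir, name)

  # -- data --------------------------------------------------------------
  paths <- config$survival$ipd_paths
  datasets <- if (!is.null(paths$pfs) && !is.null(paths$os)) {
    list(pfs = read_survival_csv(paths$pfs), os = read_survival_csv(paths$os))
  } else {
    specs <- config_cohort_specs(config, seed = seed)
    lapply(specs, simulate_ipd)
  }

  # -- fit ---------------------------------------------------------------
  fits <- lapply(datasets, fit_all_parametric)
  selected <- lapply(fits, select_best)
  if (!is.null(outdir)) {
    write_fit_report(fits$pfs, out_path("fit_report_pfs.csv"))
    write_fit_report(fits$os, out_path("fit_report_os.csv"))
  }

  # -- nma cross-check ---------------------------------------------------
  nma <- .nma_crosscheck(config, seed)

  bundle <- list(data = datasets, fits = fits, selected = selected,
                 nma = nma, log = log)

  # -- base --------------------------------------------------------------
  if (any(c("base", "scenario", "dsa", "psa") %in% stages)) {
    base <- run_cea(config, selected$pfs, selected$os)
    bundle$base <- base
    if ("base" %in% stages && !is.null(outdir)) {
      write_cea_csv(base$result, out_path("base_case.csv"))
      write_trace_csv(base$intervention, out_path("trace_intervention.csv"))
      write_trace_csv(base$comparator, out_path("trace_comparator.csv"))
    }
  }

  # -- scenario ----------------------------------------------------------
  if ("scenario" %in% stages) {
    sc_config <- config
    sc_config$settings$bevacizumab_mg_per_kg <-
      config$settings$scenario_bevacizumab_mg_per_kg %||% 7.5
    bundle$scenario <- run_cea(sc_config, selected$pfs, selected$os)
    if (!is.null(outdir)) {
      write_cea_csv(bundle$scenario$result, out_path("scenario.csv"))
    }
  }

  # -- dsa ---------------------------------------------------------------
  if ("dsa" %in% stages) {
    bundle$dsa <- one_way_dsa(config, selected$pfs, selected$os)
    if (!is.null(outdir)) {
      write_tornado_csv(bundle$dsa, out_path("tornado.csv"))
    }
  }

  # -- psa ---------------------------------------------------------------
  if ("psa" %in% stages) {
    bundle$psa <- run_psa(config, selected$pfs, selected$os,
                          n_iterations = psa_iterations, seed = seed + 10L)
    if (!is.null(outdir)) {
      write_psa_draws_csv(bundle$psa, out_path("psa_draws.csv"))
      write_ceac_csv(bundle$psa, out_path("ceac.csv"))
    }
  }
  bundle
}

# Bucher + Bayesian indirect comparison per endpoint from the configured
# anchored trial effects, where both arms' effects are available.
.nma_crosscheck <- function(config, seed) {
  effs <- config$anchored_trial_effects
  if (is.null(effs)) return(NULL)
  objs <- lapply(effs, function(e) {
    trial_effect(e$trial_id, e$arm_a, e$arm_b, e$endpoint, e$hr,
                 e$ci_low %||% NULL, e$ci_high %||% NULL)
  })
  out <- list()
  for (ep in c("PFS", "OS")) {
    sub <- Filter(function(o) o$endpoint == ep, objs)
    a <- Filter(function(o) o$arm_a == config$strategies$intervention, sub)
    b <- Filter(function(o) o$arm_a == config$strategies$comparator, sub)
    if (length(a) == 1L && length(b) == 1L) {
      res <- list(bucher = bucher_indirect(a[[1]], b[[1]]))
      if (!is.null(a[[1]]$ci_low) && !is.null(b[[1]]$ci_low)) {
        res$bayesian <- bayesian_indirect(a[[1]], b[[1]], seed = seed + 20L)
      }
      out[[tolower(ep)]] <- res
    }
  }
  if (length(out)) out else NULL
}
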