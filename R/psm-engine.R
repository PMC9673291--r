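# Three-state partitioned survival model. State occupancy is read directly
# off the PFS and OS curves each cycle (PFS share = S_PFS, dead share =
# 1 - S_OS, post-progression = the difference, clamped at zero), so no
# transition probabilities are estimated. Costs, QALYs and life-years accrue
# per cycle and are discounted at a per-cycle rate derived from the annual
# rate by compounding.

DAYS_PER_MONTH <- 365.25 / 12

#' Convert an annual discount rate to a per-cycle rate
#'
#' Compound convention: `(1 + annual)^(cycle_weeks/52) - 1`. A 5% annual
#' rate over a 3-week cycle gives 0.28% per cycle (to two decimals).
#'
#' @param annual_rate non-negative annual discount rate (proportion).
#' @param cycle_weeks cycle length in weeks.
#' @return Per-cycle discount rate (proportion).
#' @export
per_cycle_discount <- function(annual_rate, cycle_weeks = 3) {
  if (!is.numeric(annual_rate) || any(annual_rate < 0)) {
    stop("`annual_rate` must be >= 0", call. = FALSE)
  }
  (1 + annual_rate)^(cycle_weeks / 52) - 1
}

#' Convert a cumulative annual incidence to a per-cycle probability
#'
#' Uniform-spread convention used for adverse-event rates: the cumulative
#' first-year incidence is divided by the number of cycles per year
#' (365/21 = 17.38 for a 3-week cycle), e.g. 23% becomes 1.32% per cycle.
#'
#' @param annual_incidence cumulative incidence over the year, in `[0, 1]`.
#' @param cycles_per_year cycles per year (default 365/21).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_probability <- function(annual_incidence,
                                        cycles_per_year = 365 / 21) {
  if (!is.numeric(annual_incidence) || any(annual_incidence < 0) ||
      any(annual_incidence > 1)) {
    stop("`annual_incidence` must be in [0, 1]", call. = FALSE)
  }
  annual_incidence / cycles_per_year
}

#' Per-cycle acquisition cost of a drug regimen
#'
#' Supports the three dosing patterns in the model, with whole-vial wastage
#' for intravenous drugs:
#' * `flat_iv`: fixed dose per cycle; cost = `ceiling(dose_mg/vial_mg)` vials
#'   times the vial price.
#' * `weight_iv`: weight-based dose; cost =
#'   `ceiling(weight * mg_per_kg / vial_mg)` vials times the vial price.
#' * `oral_daily`: daily tablets; cost = `(daily_mg/unit_mg)` units times
#'   `days_per_cycle` times the unit price.
#'
#' @param regimen list of component lists, each with a `type` field
#'   (`"flat_iv"`, `"weight_iv"`, `"oral_daily"`) and the fields named above
#'   (`vial_cost` / `unit_cost` for prices; `days_per_cycle` defaults to 21).
#' @param body_weight_kg patient body weight in kg (needed for
#'   weight-based components).
#' @return Total drug cost per cycle.
#' @export
drug_cost_per_cycle <- function(regimen, body_weight_kg = 65) {
  if (body_weight_kg <= 0) stop("`body_weight_kg` must be > 0", call. = FALSE)
  total <- 0
  for (comp in regimen) {
    if (is.null(comp$type)) stop("regimen component lacks `type`", call. = FALSE)
    total <- total + switch(comp$type,
      flat_iv = ceiling(comp$dose_mg / comp$vial_mg) * comp$vial_cost,
      weight_iv = ceiling(body_weight_kg * comp$mg_per_kg / comp$vial_mg) *
        comp$vial_cost,
      oral_daily = (comp$daily_mg / comp$unit_mg) *
        (comp$days_per_cycle %||% 21) * comp$unit_cost,
      stop("unknown regimen component type: '", comp$type, "'", call. = FALSE)
    )
  }
  total
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Define a treatment strategy for the partitioned survival model
#'
#' @param name strategy label.
#' @param pfs_model,os_model [survival_model()]s for the two endpoint curves.
#' @param drug_cost_per_cycle,admin_cost_per_cycle per-cycle acquisition and
#'   administration cost while on treatment in the progression-free state.
#' @param followup_cost_per_cycle per-cycle follow-up/monitoring cost for
#'   alive patients (both states).
#' @param subsequent_cost_per_cycle per-cycle subsequent-treatment cost in
#'   the post-progression state.
#' @param treatment_cap_cycles cycle after which drug and administration
#'   costs stop even without progression (`Inf` = treat until progression).
#' @param ae_profile `data.frame` with columns `name`, `prob` (per-cycle
#'   probability), `cost` (management cost per event) and `disutility`
#'   (utility decrement per event, <= 0), applied to progression-free
#'   occupancy during the adverse-event window.
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(name, pfs_model, os_model,
                                drug_cost_per_cycle, admin_cost_per_cycle,
                                followup_cost_per_cycle,
                                subsequent_cost_per_cycle,
                                treatment_cap_cycles = Inf,
                                ae_profile = NULL) {
  stopifnot(inherits(pfs_model, "survival_model"),
            inherits(os_model, "survival_model"))
  costs <- c(drug_cost_per_cycle, admin_cost_per_cycle,
             followup_cost_per_cycle, subsequent_cost_per_cycle)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  if (treatment_cap_cycles <= 0) {
    stop("`treatment_cap_cycles` must be > 0", call. = FALSE)
  }
  if (is.null(ae_profile)) {
    ae_profile <- data.frame(name = character(0), prob = numeric(0),
                             cost = numeric(0), disutility = numeric(0))
  }
  if (any(ae_profile$prob < 0 | ae_profile$prob > 1)) {
    stop("AE probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, pfs_model = pfs_model, os_model = os_model,
         drug_cost_per_cycle = drug_cost_per_cycle,
         admin_cost_per_cycle = admin_cost_per_cycle,
         followup_cost_per_cycle = followup_cost_per_cycle,
         subsequent_cost_per_cycle = subsequent_cost_per_cycle,
         treatment_cap_cycles = treatment_cap_cycles,
         ae_profile = ae_profile),
    class = "strategy_definition"
  )
}

#' Economic settings of the partitioned survival model
#'
#' @param cycle_weeks model cycle length in weeks (3 = the treatment cycle).
#' @param horizon_cycles number of cycles; the default 522 three-week cycles
#'   is a 30-year horizon, effectively lifetime for this population.
#' @param annual_discount annual discount rate for costs and outcomes.
#' @param per_cycle_discount_rate per-cycle rate; derived from
#'   `annual_discount` by [per_cycle_discount()] unless given explicitly
#'   (the explicit form is used by sensitivity analyses that vary the
#'   per-cycle rate directly).
#' @param utility_pfs,utility_pp health-state utilities in `[0, 1]` with
#'   `utility_pp <= utility_pfs`.
#' @param end_of_life_cost one-off terminal-care cost applied to each
#'   cycle's incident deaths.
#' @param ae_window_cycles number of cycles over which adverse events occur
#'   (default 365/21, i.e. the first year; the fractional last cycle gets a
#'   proportional weight).
#' @param wtp_thresholds willingness-to-pay thresholds ($/QALY) carried
#'   through to reporting.
#' @param half_cycle_correction if `TRUE`, accruals use the mean of the
#'   start- and end-of-cycle occupancies instead of the end-of-cycle value.
#' @return An object of class `econ_settings`.
#' @export
econ_settings <- function(cycle_weeks = 3, horizon_cycles = 522,
                          annual_discount = 0.05,
                          per_cycle_discount_rate = NULL,
                          utility_pfs = 0.745, utility_pp = 0.678,
                          end_of_life_cost = 2132.67,
                          ae_window_cycles = 365 / 21,
                          wtp_thresholds = c(12516, 37547),
                          half_cycle_correction = FALSE) {
  if (horizon_cycles < 1) stop("`horizon_cycles` must be >= 1", call. = FALSE)
  if (is.null(per_cycle_discount_rate)) {
    per_cycle_discount_rate <- per_cycle_discount(annual_discount, cycle_weeks)
  }
  if (per_cycle_discount_rate < 0) {
    stop("discount rate must be >= 0", call. = FALSE)
  }
  if (utility_pfs < 0 || utility_pfs > 1 || utility_pp < 0 || utility_pp > 1) {
    stop("utilities must be in [0, 1]", call. = FALSE)
  }
  if (utility_pp > utility_pfs) {
    stop("`utility_pp` must be <= `utility_pfs`", call. = FALSE)
  }
  structure(
    list(cycle_weeks = cycle_weeks, horizon_cycles = as.integer(horizon_cycles),
         annual_discount = annual_discount,
         per_cycle_discount_rate = per_cycle_discount_rate,
         utility_pfs = utility_pfs, utility_pp = utility_pp,
         end_of_life_cost = end_of_life_cost,
         ae_window_cycles = ae_window_cycles,
         wtp_thresholds = wtp_thresholds,
         half_cycle_correction = half_cycle_correction),
    class = "econ_settings"
  )
}

#' Run the partitioned survival cohort trace for one strategy
#'
#' At cycle `k` (time `t_k = k` cycle lengths, in months) the cohort is
#' partitioned as progression-free = `min(S_PFS, S_OS)`, dead = `1 - S_OS`,
#' post-progression = `max(0, S_OS - S_PFS)`. Per-cycle flows use the
#' end-of-cycle occupancy (or the cycle mean under half-cycle correction):
#' drug and administration costs on progression-free occupancy while within
#' the treatment cap; follow-up cost on alive occupancy; subsequent-treatment
#' cost on post-progression occupancy; adverse-event costs and disutilities
#' on progression-free occupancy during the adverse-event window;
#' end-of-life cost on each cycle's new deaths. Every flow in cycle `k` is
#' discounted by `(1 + r)^(-k)`.
#'
#' If the progression-free curve exceeds the overall-survival curve by more
#' than 0.05 anywhere on the horizon (a structural inconsistency of the two
#' fits) a warning is issued; smaller crossings are silently clamped.
#'
#' @param strategy a [strategy_definition()].
#' @param settings an [econ_settings()].
#' @return An object of class `cohort_trace`: a `data.frame` with one row
#'   per cycle (occupancies, discounted per-category costs, discounted QALYs
#'   and life-years) carrying the strategy name, settings and total
#'   accumulators as attributes (see [trace_totals()]).
#' @export
run_trace <- function(strategy, settings) {
  stopifnot(inherits(strategy, "strategy_definition"),
            inherits(settings, "econ_settings"))
  H <- settings$horizon_cycles
  cycle_months <- settings$cycle_weeks * 7 / DAYS_PER_MONTH
  cycle_years <- cycle_months / 12
  k <- 0:H
  t_k <- k * cycle_months

  s_pfs <- survival_at(strategy$pfs_model, t_k)
  s_os <- survival_at(strategy$os_model, t_k)
  excess <- max(s_pfs - s_os)
  if (excess > 0.05) {
    warning("PFS curve exceeds OS curve by up to ", round(excess, 3),
            " on the horizon; occupancy clamped at 0", call. = FALSE)
  }

  pfs <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pp <- pmax(0, s_os - s_pfs)
  new_deaths <- c(0, diff(dead))

  # per-cycle accrual weights, cycles 1..H
  kk <- 1:H
  occ <- function(x) {
    if (settings$half_cycle_correction) {
      (x[kk] + x[kk + 1]) / 2
    } else {
      x[kk + 1]
    }
  }
  pfs_w <- occ(pfs)
  pp_w <- occ(pp)
  alive_w <- pfs_w + pp_w
  deaths_w <- new_deaths[kk + 1]

  disc <- (1 + settings$per_cycle_discount_rate)^(-kk)
  on_treat <- as.numeric(kk <= strategy$treatment_cap_cycles)
  ae_w <- pmin(1, pmax(0, settings$ae_window_cycles - (kk - 1)))

  ae_cost_rate <- sum(strategy$ae_profile$prob * strategy$ae_profile$cost)
  ae_dis_rate <- sum(strategy$ae_profile$prob * strategy$ae_profile$disutility)

  cost_drug <- disc * strategy$drug_cost_per_cycle * pfs_w * on_treat
  cost_admin <- disc * strategy$admin_cost_per_cycle * pfs_w * on_treat
  cost_followup <- disc * strategy$followup_cost_per_cycle * alive_w
  cost_subsequent <- disc * strategy$subsequent_cost_per_cycle * pp_w
  cost_ae <- disc * ae_cost_rate * pfs_w * ae_w
  cost_eol <- disc * settings$end_of_life_cost * deaths_w

  qaly <- disc * (settings$utility_pfs * pfs_w + settings$utility_pp * pp_w +
                    ae_dis_rate * pfs_w * ae_w) * cycle_years
  ly <- disc * alive_w * cycle_years

  trace <- data.frame(
    cycle = kk, time_months = t_k[kk + 1],
    pfs = pfs[kk + 1], pp = pp[kk + 1], dead = dead[kk + 1],
    new_deaths = deaths_w,
    cost_drug = cost_drug, cost_admin = cost_admin,
    cost_followup = cost_followup, cost_subsequent = cost_subsequent,
    cost_ae = cost_ae, cost_eol = cost_eol,
    qaly = qaly, ly = ly
  )
  totals <- list(
    cost = sum(cost_drug, cost_admin, cost_followup, cost_subsequent,
               cost_ae, cost_eol),
    cost_by_category = c(drug = sum(cost_drug), admin = sum(cost_admin),
                         followup = sum(cost_followup),
                         subsequent = sum(cost_subsequent),
                         ae = sum(cost_ae), eol = sum(cost_eol)),
    qaly = sum(qaly), ly = sum(ly)
  )
  structure(trace, class = c("cohort_trace", "data.frame"),
            strategy_name = strategy$name, totals = totals,
            settings = settings)
}

#' Total discounted cost, QALYs and life-years of a trace
#'
#' @param trace a [run_trace()] result.
#' @return List with `cost`, `cost_by_category`, `qaly`, `ly`.
#' @export
trace_totals <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  attr(trace, "totals")
}

#' Incremental cost-effectiveness summary from per-strategy totals
#'
#' ICER = (cost_a - cost_b) / (qaly_a - qaly_b) when the incremental QALYs
#' are non-zero; dominance is labelled instead of reported as a ratio:
#' `"dominant"` (cheaper and more effective), `"dominated"` (costlier and
#' less effective), `"undefined"` (no QALY difference).
#'
#' @param cost_a,qaly_a totals for the strategy of interest.
#' @param cost_b,qaly_b totals for the comparator.
#' @return List with `delta_cost`, `delta_qaly`, `icer` (`NA` unless status
#'   is `"icer"`) and `status`.
#' @export
incremental_summary <- function(cost_a, qaly_a, cost_b, qaly_b) {
  dc <- cost_a - cost_b
  dq <- qaly_a - qaly_b
  if (dq == 0) {
    list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
         status = "undefined")
  } else if (dc < 0 && dq > 0) {
    list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
         status = "dominant")
  } else if (dc > 0 && dq < 0) {
    list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
         status = "dominated")
  } else {
    list(delta_cost = dc, delta_qaly = dq, icer = dc / dq, status = "icer")
  }
}

#' Compare two cohort traces
#'
#' @param intervention,comparator [run_trace()] results sharing settings;
#'   the ICER is for the intervention relative to the comparator.
#' @return An object of class `cea_result`: list with a per-strategy
#'   `summary` data.frame (name, cost, qaly, ly) and the incremental
#'   `delta_cost`, `delta_qaly`, `icer`, `status`.
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "cohort_trace"),
            inherits(comparator, "cohort_trace"))
  ti <- trace_totals(intervention)
  tc <- trace_totals(comparator)
  inc <- incremental_summary(ti$cost, ti$qaly, tc$cost, tc$qaly)
  structure(
    c(list(summary = data.frame(
        strategy = c(attr(intervention, "strategy_name"),
                     attr(comparator, "strategy_name")),
        cost = c(ti$cost, tc$cost),
        qaly = c(ti$qaly, tc$qaly),
        ly = c(ti$ly, tc$ly))),
      inc),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness comparison\n")
  s <- x$summary
  s$cost <- round(s$cost)
  s$qaly <- round(s$qaly, 3)
  s$ly <- round(s$ly, 3)
  print(s, row.names = FALSE)
  cat(sprintf("\nIncremental cost: $%s\nIncremental QALYs: %.3f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (x$status == "icer") {
    cat(sprintf("ICER: $%s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat("ICER:", x$status, "\n")
  }
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle with occupancies and discounted per-category flows.
#'
#' @param trace a [run_trace()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a cost-effectiveness comparison to CSV
#'
#' Columns mirror a standard base-case results table: strategy, cost, QALY,
#' LYs, ICER (reported on the intervention row only).
#'
#' @param result a [compare_strategies()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(result, path) {
  stopifnot(inherits(result, "cea_result"))
  out <- result$summary
  out$icer <- c(if (result$status == "icer") result$icer else NA, NA)
  out$status <- c(result$status, NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
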