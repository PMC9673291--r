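# Shared fixtures. Everything is generated in code; nothing is read from
# disk except the packaged configuration.

# A parametric_fit object built directly from known parameters (bypasses
# fitting; used for toy traces with exactly known survivor functions).
toy_fit <- function(family, params) {
  structure(
    list(family = psmcea::normalize_family(family), params = params,
         loglik = NA_real_, aic = NA_real_, bic = NA_real_,
         n = NA_integer_, n_events = NA_integer_, vcov = NULL),
    class = "parametric_fit"
  )
}

# Toy strategy: exponential PFS hitting S = 0.5 at the first cycle boundary
# and Weibull OS hitting S = {0.8, 0.5} at the first two cycle boundaries,
# so occupancy at cycles 1 and 2 is exactly PFS {0.5, 0.25}, OS {0.8, 0.5}.
toy_cycle_months <- function(cycle_weeks = 3) cycle_weeks * 7 / (365.25 / 12)

toy_pfs_fit <- function(cycle_weeks = 3) {
  t1 <- toy_cycle_months(cycle_weeks)
  toy_fit("exponential", c(rate = log(2) / t1))
}

toy_os_fit <- function(cycle_weeks = 3) {
  t1 <- toy_cycle_months(cycle_weeks)
  shape <- log(log(0.5) / log(0.8)) / log(2)
  scale <- t1 / (-log(0.8))^(1 / shape)
  toy_fit("weibull", c(shape = shape, scale = scale))
}

toy_strategy <- function(name = "toy", cycle_weeks = 3, drug = 100,
                         admin = 10, followup = 5, subsequent = 50,
                         cap = Inf, ae = NULL) {
  psmcea::strategy_definition(
    name = name,
    pfs_model = psmcea::survival_model(toy_pfs_fit(cycle_weeks)),
    os_model = psmcea::survival_model(toy_os_fit(cycle_weeks)),
    drug_cost_per_cycle = drug, admin_cost_per_cycle = admin,
    followup_cost_per_cycle = followup, subsequent_cost_per_cycle = subsequent,
    treatment_cap_cycles = cap, ae_profile = ae
  )
}

# Independent brute-force re-implementation of the cohort trace totals:
# scalar loop over cycles, recomputing every flow from first principles.
# Used only as a test oracle.
brute_force_totals <- function(strategy, settings) {
  H <- settings$horizon_cycles
  cm <- settings$cycle_weeks * 7 / (365.25 / 12)
  cy <- cm / 12
  r <- settings$per_cycle_discount_rate
  ae_cost <- sum(strategy$ae_profile$prob * strategy$ae_profile$cost)
  ae_dis <- sum(strategy$ae_profile$prob * strategy$ae_profile$disutility)
  total_cost <- 0; total_qaly <- 0; total_ly <- 0
  prev_dead <- 0
  for (k in 1:H) {
    s_pfs_end <- psmcea::survival_at(strategy$pfs_model, k * cm)
    s_os_end <- psmcea::survival_at(strategy$os_model, k * cm)
    pfs_end <- min(s_pfs_end, s_os_end)
    pp_end <- max(0, s_os_end - s_pfs_end)
    dead_end <- 1 - s_os_end
    if (settings$half_cycle_correction) {
      s_pfs_start <- psmcea::survival_at(strategy$pfs_model, (k - 1) * cm)
      s_os_start <- psmcea::survival_at(strategy$os_model, (k - 1) * cm)
      pfs <- (min(s_pfs_start, s_os_start) + pfs_end) / 2
      pp <- (max(0, s_os_start - s_pfs_start) + pp_end) / 2
    } else {
      pfs <- pfs_end
      pp <- pp_end
    }
    new_dead <- dead_end - prev_dead
    prev_dead <- dead_end
    disc <- (1 + r)^(-k)
    on_treat <- if (k <= strategy$treatment_cap_cycles) 1 else 0
    aew <- min(1, max(0, settings$ae_window_cycles - (k - 1)))
    cost <- strategy$drug_cost_per_cycle * pfs * on_treat +
      strategy$admin_cost_per_cycle * pfs * on_treat +
      strategy$followup_cost_per_cycle * (pfs + pp) +
      strategy$subsequent_cost_per_cycle * pp +
      ae_cost * pfs * aew +
      settings$end_of_life_cost * new_dead
    qaly <- (settings$utility_pfs * pfs + settings$utility_pp * pp +
               ae_dis * pfs * aew) * cy
    total_cost <- total_cost + disc * cost
    total_qaly <- total_qaly + disc * qaly
    total_ly <- total_ly + disc * (pfs + pp) * cy
  }
  list(cost = total_cost, qaly = total_qaly, ly = total_ly)
}

# Packaged configuration with a shortened horizon and a small simulated
# cohort, for fast sensitivity-analysis tests. The fitted curves are cached
# per session.
.fixture_env <- new.env(parent = emptyenv())

fast_config <- function(horizon = 150L) {
  cfg <- psmcea::read_run_config()
  cfg$settings$horizon_cycles <- horizon
  cfg
}

fixture_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    cfg <- psmcea::read_run_config()
    cfg$survival$n_patients <- 300L
    specs <- psmcea::config_cohort_specs(cfg, seed = 99L)
    .fixture_env$fits <- list(
      pfs = psmcea::fit_parametric(psmcea::simulate_ipd(specs$pfs),
                                   "lognormal"),
      os = psmcea::fit_parametric(psmcea::simulate_ipd(specs$os), "lognormal")
    )
  }
  .fixture_env$fits
}
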