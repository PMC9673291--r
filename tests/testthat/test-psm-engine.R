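# Partitioned survival engine: rate conversions, drug-cost arithmetic,
# cohort trace mechanics against hand-computed and brute-force oracles,
# and the incremental comparison.

test_that("annual discount converts to the compound per-cycle rate", {
  expect_equal(round(per_cycle_discount(0.05, 3), 4), 0.0028)
  expect_equal(per_cycle_discount(0, 3), 0)
  expect_equal(per_cycle_discount(0.05, 52), 0.05)
  expect_error(per_cycle_discount(-0.01), ">= 0")
})

test_that("annual incidences spread uniformly over the year's cycles", {
  expect_equal(round(annual_to_cycle_probability(0.23), 4), 0.0132)
  expect_equal(round(annual_to_cycle_probability(0.125), 4), 0.0072)
  expect_equal(annual_to_cycle_probability(0), 0)
  expect_error(annual_to_cycle_probability(1.2), "\\[0, 1\\]")
})

test_that("drug costs follow vial wastage and tablet arithmetic", {
  sint <- list(list(type = "flat_iv", dose_mg = 200, vial_mg = 100,
                    vial_cost = 166.92))
  expect_equal(drug_cost_per_cycle(sint), 333.84)

  lenv <- list(list(type = "oral_daily", daily_mg = 12, unit_mg = 4,
                    days_per_cycle = 21, unit_cost = 16.69))
  expect_equal(drug_cost_per_cycle(lenv), 1051.47)

  bev <- list(list(type = "weight_iv", mg_per_kg = 15, vial_mg = 100,
                   vial_cost = 177.13))
  expect_equal(drug_cost_per_cycle(bev, body_weight_kg = 65), 1771.30)
  # whole-vial wastage: 70 kg needs ceiling(10.5) = 11 vials
  expect_equal(drug_cost_per_cycle(bev, body_weight_kg = 70), 11 * 177.13)

  expect_error(drug_cost_per_cycle(list(list(type = "patch"))), "unknown")
  expect_error(drug_cost_per_cycle(bev, body_weight_kg = 0), "> 0")
})

test_that("a two-cycle toy trace matches the hand-computed accrual", {
  strat <- toy_strategy(drug = 100, admin = 10, followup = 5,
                        subsequent = 50)
  settings <- econ_settings(horizon_cycles = 2, per_cycle_discount_rate = 0,
                            end_of_life_cost = 0, ae_window_cycles = 0)
  trace <- run_trace(strat, settings)
  cy <- toy_cycle_months() / 12
  # occupancy at the two cycle boundaries: PFS {.5, .25}, OS {.8, .5}
  expect_equal(trace$pfs, c(0.5, 0.25))
  expect_equal(trace$pp, c(0.3, 0.25))
  expect_equal(trace$dead, c(0.2, 0.5))
  expect_equal(trace$qaly,
               c((0.745 * 0.5 + 0.678 * 0.3) * cy,
                 (0.745 * 0.25 + 0.678 * 0.25) * cy))
  expect_equal(trace$cost_drug, c(100 * 0.5, 100 * 0.25))
  expect_equal(trace$cost_subsequent, c(50 * 0.3, 50 * 0.25))
  expect_equal(trace$cost_followup, c(5 * 0.8, 5 * 0.5))
})

test_that("the engine reproduces an independent brute-force implementation", {
  ae <- data.frame(name = c("hypertension", "proteinuria"),
                   prob = c(0.0132, 0.0035),
                   cost = c(3.42, 22.10),
                   disutility = c(-0.12, 0))
  strat <- toy_strategy(drug = 1051.47, admin = 5.13, followup = 125.26,
                        subsequent = 631.81, cap = 35, ae = ae)
  for (hcc in c(FALSE, TRUE)) {
    settings <- econ_settings(horizon_cycles = 80, annual_discount = 0.05,
                              end_of_life_cost = 2132.67,
                              half_cycle_correction = hcc)
    trace <- run_trace(strat, settings)
    got <- trace_totals(trace)
    want <- brute_force_totals(strat, settings)
    expect_equal(got$cost, want$cost, tolerance = 1e-9)
    expect_equal(got$qaly, want$qaly, tolerance = 1e-9)
    expect_equal(got$ly, want$ly, tolerance = 1e-9)
  }
})

test_that("occupancy is conserved and death is absorbing", {
  fits <- fixture_fits()
  strat <- strategy_definition(
    "s", survival_model(fits$pfs), survival_model(fits$os),
    drug_cost_per_cycle = 2105.14, admin_cost_per_cycle = 10.18,
    followup_cost_per_cycle = 125.26, subsequent_cost_per_cycle = 442.29,
    treatment_cap_cycles = 35,
    ae_profile = data.frame(name = "hypertension", prob = 0.0072,
                            cost = 3.42, disutility = -0.12)
  )
  trace <- run_trace(strat, econ_settings(horizon_cycles = 522))
  expect_true(all(abs(trace$pfs + trace$pp + trace$dead - 1) <= 1e-12))
  expect_true(all(diff(trace$dead) >= 0))
  expect_true(all(trace$pp >= 0))
})

test_that("unit utilities without discounting equate QALYs and life-years", {
  strat <- toy_strategy()
  settings <- econ_settings(horizon_cycles = 50, per_cycle_discount_rate = 0,
                            utility_pfs = 1, utility_pp = 1,
                            ae_window_cycles = 0)
  tot <- trace_totals(run_trace(strat, settings))
  expect_equal(tot$qaly, tot$ly, tolerance = 1e-12)

  # with utilities below one, QALYs fall strictly short of life-years
  tot2 <- trace_totals(run_trace(strat, econ_settings(horizon_cycles = 50)))
  expect_lt(tot2$qaly, tot2$ly)
})

test_that("identical PFS and OS curves empty the post-progression state", {
  fit <- toy_pfs_fit()
  strat <- strategy_definition(
    "s", survival_model(fit), survival_model(fit),
    drug_cost_per_cycle = 10, admin_cost_per_cycle = 1,
    followup_cost_per_cycle = 1, subsequent_cost_per_cycle = 99
  )
  trace <- run_trace(strat, econ_settings(horizon_cycles = 30))
  expect_true(all(trace$pp == 0))
  expect_equal(sum(trace$cost_subsequent), 0)
})

test_that("a PFS curve above the OS curve triggers the crossing warning", {
  strat <- strategy_definition(
    "s", survival_model(toy_os_fit()), survival_model(toy_pfs_fit()),
    drug_cost_per_cycle = 0, admin_cost_per_cycle = 0,
    followup_cost_per_cycle = 0, subsequent_cost_per_cycle = 0
  )
  expect_warning(run_trace(strat, econ_settings(horizon_cycles = 10)),
                 "clamped")
})

test_that("totals strictly decrease as the discount rate increases", {
  strat <- toy_strategy()
  totals_at <- function(rate) {
    trace_totals(run_trace(strat, econ_settings(
      horizon_cycles = 60, per_cycle_discount_rate = rate)))
  }
  rates <- c(0, 0.0028, 0.01, 0.03)
  costs <- vapply(rates, function(r) totals_at(r)$cost, numeric(1))
  qalys <- vapply(rates, function(r) totals_at(r)$qaly, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("totals converge once the cohort is effectively extinct", {
  fits <- fixture_fits()
  strat <- strategy_definition(
    "s", survival_model(fits$pfs), survival_model(fits$os),
    drug_cost_per_cycle = 2105.14, admin_cost_per_cycle = 10.18,
    followup_cost_per_cycle = 125.26, subsequent_cost_per_cycle = 442.29,
    treatment_cap_cycles = 35
  )
  # find the horizon at which alive occupancy first falls below 0.1% ...
  probe <- run_trace(strat, econ_settings(horizon_cycles = 2000))
  h_star <- min(which(probe$pfs + probe$pp < 0.001))
  expect_lt(h_star, 2000)
  # ... and check that extending the horizon beyond it barely moves totals
  t1 <- trace_totals(run_trace(strat, econ_settings(horizon_cycles = h_star)))
  t2 <- trace_totals(run_trace(strat,
                               econ_settings(horizon_cycles = h_star + 300L)))
  expect_lt(abs(t2$cost - t1$cost) / t1$cost, 0.001)
  expect_lt(abs(t2$qaly - t1$qaly) / t1$qaly, 0.001)
})

test_that("the treatment cap stops drug and administration costs only", {
  strat_capped <- toy_strategy(cap = 5)
  strat_free <- toy_strategy(cap = Inf)
  settings <- econ_settings(horizon_cycles = 20, per_cycle_discount_rate = 0)
  tc <- run_trace(strat_capped, settings)
  tf <- run_trace(strat_free, settings)
  expect_true(all(tc$cost_drug[6:20] == 0))
  expect_equal(tc$cost_drug[1:5], tf$cost_drug[1:5])
  expect_equal(tc$cost_followup, tf$cost_followup)
  expect_equal(tc$qaly, tf$qaly)
})

test_that("incremental summaries label dominance instead of dividing", {
  # printed-totals arithmetic
  inc <- incremental_summary(33102, 1.431, 21037, 0.938)
  expect_equal(inc$delta_cost, 12065)
  expect_equal(inc$delta_qaly, 0.493)
  expect_equal(inc$icer, 12065 / 0.493)

  expect_equal(incremental_summary(10, 1, 20, 1)$status, "undefined")
  expect_equal(incremental_summary(10, 2, 20, 1)$status, "dominant")
  expect_equal(incremental_summary(20, 1, 10, 2)$status, "dominated")
  expect_equal(incremental_summary(20, 2, 10, 1)$status, "icer")
})

test_that("comparing identical traces yields no increments", {
  strat <- toy_strategy()
  settings <- econ_settings(horizon_cycles = 10)
  tr <- run_trace(strat, settings)
  res <- compare_strategies(tr, tr)
  expect_equal(res$delta_cost, 0)
  expect_equal(res$delta_qaly, 0)
  expect_equal(res$status, "undefined")
})

test_that("traces and comparisons export to CSV", {
  strat <- toy_strategy()
  settings <- econ_settings(horizon_cycles = 10)
  tr <- run_trace(strat, settings)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, p1)
  tab <- read.csv(p1)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("pfs", "pp", "dead", "qaly", "ly") %in% names(tab)))

  strat2 <- toy_strategy(drug = 500)
  res <- compare_strategies(run_trace(strat2, settings), tr)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cea_csv(res, p2)
  tab2 <- read.csv(p2)
  expect_equal(names(tab2), c("strategy", "cost", "qaly", "ly", "icer",
                              "status"))
})
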