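# Deterministic and probabilistic sensitivity analysis.

test_that("parameter specifications cover the model inputs with valid ranges", {
  cfg <- read_run_config()
  specs <- parameter_specs(cfg)
  expect_true(all(specs$low <= specs$base & specs$base <= specs$high))
  expect_true(all(c("utility.pfs", "utility.pp", "hr.pfs", "hr.os",
                    "drug_price.bevacizumab_100mg", "end_of_life_cost",
                    "ae_prob.lenvatinib.hypertension",
                    "discount.per_cycle") %in% specs$role))
  # domain-driven distribution families
  expect_true(all(specs$psa_family[grepl("^(drug_price|.*cost)", specs$role)]
                  == "gamma"))
  expect_true(all(specs$psa_family[grepl("^(utility|ae_prob|ae_disutility)",
                                         specs$role)] == "beta"))
  expect_true(all(specs$psa_family[grepl("^hr", specs$role)] == "lognormal"))
})

test_that("apply_parameter reaches every advertised role", {
  cfg <- read_run_config()
  specs <- parameter_specs(cfg)
  for (i in seq_len(nrow(specs))) {
    mod <- apply_parameter(cfg, specs$role[i], specs$high[i])
    re <- parameter_specs(mod)
    expect_equal(re$base[re$role == specs$role[i]], specs$high[i])
  }
  expect_error(apply_parameter(cfg, "not.a.role", 1), "unknown role")
})

test_that("moment matching reproduces the target mean and sd", {
  specs <- data.frame(
    name = c("eol", "u_pfs", "hr_os"),
    role = c("end_of_life_cost", "utility.pfs", "hr.os"),
    base = c(2132.67, 0.745, 0.618),
    low = c(888.10, 0.730, 0.546),
    high = c(6108.44, 0.760, 0.708),
    psa_family = c("gamma", "beta", "lognormal")
  )
  draws <- draw_parameter_matrix(specs, 50000, seed = 123)
  z <- qnorm(0.975)

  # gamma: mean = base, sd = (high - low) / (2z)
  s_eol <- (6108.44 - 888.10) / (2 * z)
  expect_equal(mean(draws[, "end_of_life_cost"]), 2132.67,
               tolerance = 3 * s_eol / sqrt(50000) / 2132.67)
  expect_equal(sd(draws[, "end_of_life_cost"]), s_eol, tolerance = 0.02)
  # moment-matched shape/rate reproduce the targets analytically
  shape <- (2132.67 / s_eol)^2
  rate <- 2132.67 / s_eol^2
  expect_equal(shape / rate, 2132.67)
  expect_equal(sqrt(shape) / rate, s_eol)

  # beta: mean within 3 standard errors of the base utility
  s_u <- (0.760 - 0.730) / (2 * z)
  expect_equal(mean(draws[, "utility.pfs"]), 0.745,
               tolerance = 3 * s_u / sqrt(50000) / 0.745)

  # log-normal: median at the base hazard ratio
  expect_equal(median(draws[, "hr.os"]), 0.618, tolerance = 0.01)
})

test_that("degenerate ranges collapse to the base value", {
  specs <- data.frame(name = "d", role = "ae_disutility.platelet_count_decreased",
                      base = 0, low = 0, high = 0, psa_family = "beta")
  draws <- draw_parameter_matrix(specs, 100, seed = 1)
  expect_true(all(draws == 0))
})

test_that("negative disutilities are drawn on their magnitude", {
  specs <- data.frame(name = "d", role = "ae_disutility.hypertension",
                      base = -0.12, low = -0.14, high = -0.10,
                      psa_family = "beta")
  draws <- draw_parameter_matrix(specs, 20000, seed = 4)
  expect_true(all(draws < 0))
  expect_equal(mean(draws), -0.12, tolerance = 0.005)
})

test_that("infeasible beta moment matching clips with a warning", {
  specs <- data.frame(name = "p", role = "utility.pp", base = 0.01,
                      low = 0, high = 0.9, psa_family = "beta")
  expect_warning(draws <- draw_parameter_matrix(specs, 1000, seed = 2),
                 "clipping")
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("one-way analysis ranks parameters like exhaustive enumeration", {
  cfg <- fast_config()
  fits <- fixture_fits()
  specs <- parameter_specs(cfg)
  keep <- specs[specs$role %in% c("utility.pp", "hr.os",
                                  "drug_price.bevacizumab_100mg",
                                  "subsequent_cost.lenvatinib"), ]
  tornado <- one_way_dsa(cfg, fits$pfs, fits$os, specs = keep)
  expect_s3_class(tornado, "tornado_table")
  expect_equal(nrow(tornado), 4)

  # brute-force enumeration of the same bound evaluations
  widths <- vapply(seq_len(nrow(keep)), function(i) {
    icer_at <- function(v) {
      run_cea(apply_parameter(cfg, keep$role[i], v),
              fits$pfs, fits$os)$result$icer
    }
    abs(icer_at(keep$high[i]) - icer_at(keep$low[i]))
  }, numeric(1))
  expect_equal(tornado$role, keep$role[order(-widths)])
  expect_equal(sort(tornado$width, decreasing = TRUE), sort(widths,
               decreasing = TRUE))
})

test_that("a zero-width parameter yields a zero-width tornado bar", {
  cfg <- fast_config()
  fits <- fixture_fits()
  specs <- parameter_specs(cfg)
  degenerate <- specs[specs$role == "ae_cost.hypertension", ]
  degenerate$low <- degenerate$high <- degenerate$base
  tornado <- one_way_dsa(cfg, fits$pfs, fits$os, specs = degenerate)
  expect_equal(tornado$width, 0)
  expect_equal(tornado$icer_low, tornado$icer_high)
})

test_that("raising a comparator-only cost lowers the ICER monotonically", {
  cfg <- fast_config()
  fits <- fixture_fits()
  role <- "subsequent_cost.lenvatinib"
  vals <- c(505.45, 631.81, 758.17)
  icers <- vapply(vals, function(v) {
    run_cea(apply_parameter(cfg, role, v), fits$pfs, fits$os)$result$icer
  }, numeric(1))
  expect_true(all(diff(icers) < 0))
})

test_that("degenerate PSA distributions reproduce the base case exactly", {
  cfg <- fast_config()
  fits <- fixture_fits()
  specs <- parameter_specs(cfg)
  specs$low <- specs$high <- specs$base
  base <- run_cea(cfg, fits$pfs, fits$os)$result
  psa <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 5, seed = 1,
                 specs = specs)
  expect_true(all(psa$draws$delta_cost == base$delta_cost))
  expect_true(all(psa$draws$delta_qaly == base$delta_qaly))
})

test_that("the acceptability curve obeys its definition", {
  cfg <- fast_config()
  fits <- fixture_fits()
  psa <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 200, seed = 8)
  expect_equal(psa$n_failures, 0)

  # CEAC at lambda = 0 is the fraction of cost-saving draws
  expect_equal(ceac_probability(psa, 0), mean(psa$draws$delta_cost < 0))
  # monotone non-decreasing whenever all draws gain QALYs
  if (all(psa$draws$delta_qaly > 0)) {
    expect_true(all(diff(psa$ceac$probability) >= 0))
  }
  # two-strategy complement: comparator probability is 1 - CEAC up to ties
  lambda <- 25000
  p_int <- ceac_probability(psa, lambda)
  p_cmp <- mean(lambda * psa$draws$delta_qaly - psa$draws$delta_cost <= 0)
  expect_equal(p_int + p_cmp, 1)
  # crossover sits where the curve first reaches one half
  if (!is.na(psa$crossover_wtp)) {
    expect_gte(ceac_probability(psa, psa$crossover_wtp), 0.5)
    below <- psa$ceac$wtp < psa$crossover_wtp
    expect_true(all(psa$ceac$probability[below] < 0.5))
  }
})

test_that("the PSA is bit-reproducible under a fixed seed", {
  cfg <- fast_config()
  fits <- fixture_fits()
  p1 <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 50, seed = 42)
  p2 <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 50, seed = 42)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  p3 <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 50, seed = 43)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("sensitivity outputs export to CSV and plots build", {
  cfg <- fast_config()
  fits <- fixture_fits()
  specs <- parameter_specs(cfg)
  tornado <- one_way_dsa(cfg, fits$pfs, fits$os,
                         specs = specs[specs$role %in%
                                         c("utility.pp", "hr.os"), ])
  psa <- run_psa(cfg, fits$pfs, fits$os, n_iterations = 20, seed = 2)
  d <- withr::local_tempdir()
  write_tornado_csv(tornado, file.path(d, "tornado.csv"))
  write_psa_draws_csv(psa, file.path(d, "draws.csv"))
  write_ceac_csv(psa, file.path(d, "ceac.csv"))
  expect_equal(nrow(read.csv(file.path(d, "draws.csv"))), 20)
  expect_s3_class(plot_tornado(tornado), "ggplot")
  expect_s3_class(plot_ce_plane(psa), "ggplot")
  expect_s3_class(plot_ceac(psa), "ggplot")
})
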