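# Sensitivity analysis: one-way deterministic analysis with tornado ranking
# and probabilistic sensitivity analysis (PSA) with cost-effectiveness
# acceptability curves. Parameter distributions follow the usual
# health-economic conventions: probabilities and utilities ~ beta, costs ~
# gamma (both moment-matched to the base value and the range-implied
# standard deviation), hazard ratios ~ log-normal on the log scale.

#' Enumerate the model's uncertain parameters
#'
#' Builds one specification per configurable parameter: name, a `role`
#' string addressing the parameter inside the configuration, base value,
#' low/high bounds (95% interval when published, otherwise the +/-20%
#' convention already encoded in the configuration ranges) and the PSA
#' distribution family implied by the parameter's domain.
#'
#' @param config a `run_config`.
#' @return A `data.frame` with columns `name`, `role`, `base`, `low`,
#'   `high`, `psa_family`.
#' @export
parameter_specs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  add <- function(name, role, block, family) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, role = role, base = block$base, low = block$low,
      high = block$high, psa_family = family
    )
  }
  for (nm in names(config$drug_prices)) {
    add(paste("Price of", nm), paste0("drug_price.", nm),
        config$drug_prices[[nm]], "gamma")
  }
  for (nm in names(config$subsequent_costs)) {
    add(paste("Subsequent treatment cost,", nm),
        paste0("subsequent_cost.", nm), config$subsequent_costs[[nm]],
        "gamma")
  }
  add("End-of-life care cost", "end_of_life_cost", config$end_of_life_cost,
      "gamma")
  for (nm in names(config$followup_costs)) {
    add(paste("Follow-up cost,", nm), paste0("followup_cost.", nm),
        config$followup_costs[[nm]], "gamma")
  }
  for (nm in names(config$admin_costs)) {
    add(paste("Administration cost,", nm), paste0("admin_cost.", nm),
        config$admin_costs[[nm]], "gamma")
  }
  for (nm in names(config$ae_costs)) {
    add(paste("AE management cost,", nm), paste0("ae_cost.", nm),
        config$ae_costs[[nm]], "gamma")
  }
  for (nm in names(config$ae_disutilities)) {
    add(paste("AE disutility,", nm), paste0("ae_disutility.", nm),
        config$ae_disutilities[[nm]], "beta")
  }
  for (arm in names(config$ae_probabilities)) {
    for (nm in names(config$ae_probabilities[[arm]])) {
      add(paste0("AE probability, ", arm, ", ", nm),
          paste0("ae_prob.", arm, ".", nm),
          config$ae_probabilities[[arm]][[nm]], "beta")
    }
  }
  add("Utility, progression-free", "utility.pfs", config$utilities$pfs,
      "beta")
  add("Utility, post-progression", "utility.pp", config$utilities$pp, "beta")
  for (ep in c("pfs", "os")) {
    h <- config$hazard_ratios[[ep]]
    add(paste("Hazard ratio,", toupper(ep)), paste0("hr.", ep),
        list(base = h$hr, low = h$ci_low, high = h$ci_high), "lognormal")
  }
  dr <- config$discount_per_cycle
  dr_base <- dr$override %||%
    per_cycle_discount(config$settings$annual_discount,
                       config$settings$cycle_weeks)
  add("Discount rate (per cycle)", "discount.per_cycle",
      list(base = dr_base, low = min(dr$low, dr_base),
           high = max(dr$high, dr_base)), "beta")
  out <- do.call(rbind, rows)
  bad <- out$name[out$low > out$base | out$base > out$high]
  if (length(bad)) {
    stop("parameter spec violates low <= base <= high: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  out
}

#' Set one parameter of a configuration by role
#'
#' @param config a `run_config`.
#' @param role a role string as produced by [parameter_specs()], e.g.
#'   `"utility.pp"`, `"drug_price.bevacizumab_100mg"`,
#'   `"ae_prob.lenvatinib.hypertension"`.
#' @param value new base value.
#' @return The modified configuration.
#' @export
apply_parameter <- function(config, role, value) {
  stopifnot(inherits(config, "run_config"))
  parts <- strsplit(role, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  set_base <- function(path) {
    node <- config
    for (p in path) {
      if (is.null(node[[p]])) stop("unknown role: '", role, "'", call. = FALSE)
      node <- node[[p]]
    }
    config[[c(path, "base")]] <- value
    config
  }
  config <- switch(head,
    drug_price = set_base(c("drug_prices", parts[2])),
    subsequent_cost = set_base(c("subsequent_costs", parts[2])),
    end_of_life_cost = set_base("end_of_life_cost"),
    followup_cost = set_base(c("followup_costs", parts[2])),
    admin_cost = set_base(c("admin_costs", parts[2])),
    ae_cost = set_base(c("ae_costs", parts[2])),
    ae_disutility = set_base(c("ae_disutilities", parts[2])),
    ae_prob = set_base(c("ae_probabilities", parts[2], parts[3])),
    utility = set_base(c("utilities", parts[2])),
    hr = {
      if (is.null(config$hazard_ratios[[parts[2]]])) {
        stop("unknown role: '", role, "'", call. = FALSE)
      }
      config$hazard_ratios[[parts[2]]]$hr <- value
      # keep the interval invariant satisfied for downstream validation
      config$hazard_ratios[[parts[2]]]$ci_low <-
        min(config$hazard_ratios[[parts[2]]]$ci_low, value)
      config$hazard_ratios[[parts[2]]]$ci_high <-
        max(config$hazard_ratios[[parts[2]]]$ci_high, value)
      config
    },
    discount = {
      config$discount_per_cycle$override <- value
      config
    },
    stop("unknown role: '", role, "'", call. = FALSE)
  )
  config
}

#' One-way deterministic sensitivity analysis with tornado ranking
#'
#' Re-runs the full two-arm model once at each parameter's low and high
#' bound (all other parameters at base) and ranks parameters by the width
#' `|ICER_high - ICER_low|`. Bounds that produce a dominance or undefined
#' outcome are labelled and excluded from the width (reported as `NA`).
#'
#' @param config a `run_config`.
#' @param pfs_fit,os_fit intervention-arm `parametric_fit`s.
#' @param specs parameter specifications; defaults to
#'   [parameter_specs()] of the configuration.
#' @return A `data.frame` of class `tornado_table`, ordered by descending
#'   width, with the base-case ICER as attribute `"base_icer"`.
#' @export
one_way_dsa <- function(config, pfs_fit, os_fit,
                        specs = parameter_specs(config)) {
  base <- run_cea(config, pfs_fit, os_fit)$result
  if (base$status != "icer") {
    stop("base case does not produce an ICER (status: ", base$status, ")",
         call. = FALSE)
  }
  eval_at <- function(role, value) {
    res <- run_cea(apply_parameter(config, role, value), pfs_fit, os_fit)$result
    list(icer = if (res$status == "icer") res$icer else NA_real_,
         status = res$status)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- eval_at(specs$role[i], specs$low[i])
    hi <- eval_at(specs$role[i], specs$high[i])
    data.frame(parameter = specs$name[i], role = specs$role[i],
               base = specs$base[i], low = specs$low[i], high = specs$high[i],
               icer_low = lo$icer, icer_high = hi$icer,
               status_low = lo$status, status_high = hi$status,
               width = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado_table", "data.frame"),
            base_icer = base$icer)
}

# Moment-matched distribution draws for one parameter spec.
# sd is derived from the bounds as (high - low) / (2 * z_0.975); a zero sd
# collapses to the base value.
.draw_spec <- function(base, low, high, family, n) {
  z <- stats::qnorm(0.975)
  s <- (high - low) / (2 * z)
  if (s == 0 || family == "fixed") return(rep(base, n))
  switch(family,
    beta = {
      sign <- if (base < 0) -1 else 1
      m <- abs(base)
      if (m <= 0 || m >= 1) return(rep(base, n))
      smax <- sqrt(m * (1 - m))
      if (s >= smax) {
        warning("beta moment matching infeasible (sd ", signif(s, 3),
                " >= ", signif(smax, 3), "); clipping sd", call. = FALSE)
        s <- 0.99 * smax
      }
      nu <- m * (1 - m) / s^2 - 1
      sign * stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    gamma = {
      shape <- (base / s)^2
      rate <- base / s^2
      stats::rgamma(n, shape = shape, rate = rate)
    },
    lognormal = {
      sdlog <- (log(high) - log(low)) / (2 * z)
      stats::rlnorm(n, meanlog = log(base), sdlog = sdlog)
    },
    stop("unknown PSA family: '", family, "'", call. = FALSE)
  )
}

#' Draw parameter values from their PSA distributions
#'
#' Beta and gamma parameters are moment-matched with mean equal to the base
#' value and standard deviation `(high - low) / (2 * 1.959964)`; hazard
#' ratios are log-normal with log-mean `log(base)` and log-sd derived from
#' the interval. Negative-valued beta parameters (disutilities) are drawn on
#' their magnitude and re-signed. Draws are taken spec by spec in row
#' order, so the result is deterministic given the seed.
#'
#' @param specs a [parameter_specs()] data.frame.
#' @param n number of draws per parameter.
#' @param seed integer seed.
#' @return An `n` x `nrow(specs)` matrix, columns named by role.
#' @export
draw_parameter_matrix <- function(specs, n, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  draws <- vapply(seq_len(nrow(specs)), function(i) {
    .draw_spec(specs$base[i], specs$low[i], specs$high[i],
               specs$psa_family[i], n)
  }, numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- specs$role
  draws
}

#' Draw one sampled configuration
#'
#' Applies a single joint draw of all parameters to the configuration.
#'
#' @param config a `run_config`.
#' @param specs parameter specifications.
#' @param seed integer seed.
#' @return The sampled configuration.
#' @export
draw_parameters <- function(config, specs = parameter_specs(config), seed) {
  draws <- draw_parameter_matrix(specs, 1L, seed)
  .apply_draw(config, specs, draws[1L, ])
}

.apply_draw <- function(config, specs, values) {
  for (i in seq_len(nrow(specs))) {
    config <- apply_parameter(config, specs$role[i], values[[i]])
  }
  config
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_iterations` Monte Carlo iterations: each iteration jointly draws
#' all parameters from their PSA distributions, re-runs both arms of the
#' model and records the incremental cost and QALY pair. The
#' cost-effectiveness acceptability curve is
#' `CEAC(lambda) = P(lambda * dQ - dC > 0)` over the willingness-to-pay
#' grid, and the crossover is the smallest grid value with CEAC >= 0.5.
#'
#' Iterations that fail are recorded and skipped; more than 1% failures
#' aborts the analysis.
#'
#' @param config a `run_config`.
#' @param pfs_fit,os_fit intervention-arm `parametric_fit`s.
#' @param n_iterations number of Monte Carlo iterations (5000 in the
#'   standard analysis).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param wtp_grid increasing willingness-to-pay grid ($/QALY).
#' @param specs parameter specifications.
#' @return An object of class `psa_result`: list with `draws` (data.frame
#'   `iteration`, `delta_cost`, `delta_qaly`), `n_iterations`, `seed`,
#'   `n_failures`, `ceac` (data.frame `wtp`, `probability`) and
#'   `crossover_wtp`.
#' @export
run_psa <- function(config, pfs_fit, os_fit, n_iterations = 5000L, seed = 1L,
                    wtp_grid = seq(0, 50000, by = 500),
                    specs = parameter_specs(config)) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (any(diff(wtp_grid) <= 0)) {
    stop("`wtp_grid` must be increasing", call. = FALSE)
  }
  draws <- draw_parameter_matrix(specs, n_iterations, seed)
  dc <- dq <- rep(NA_real_, n_iterations)
  failures <- 0L
  for (it in seq_len(n_iterations)) {
    res <- tryCatch(
      run_cea(.apply_draw(config, specs, draws[it, ]), pfs_fit, os_fit)$result,
      error = function(e) NULL
    )
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > max(1, 0.01 * n_iterations)) {
        stop("more than 1% of PSA iterations failed (", failures, " of ",
             it, ")", call. = FALSE)
      }
      next
    }
    dc[it] <- res$delta_cost
    dq[it] <- res$delta_qaly
  }
  ok <- !is.na(dc)
  ceac_prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * dq[ok] - dc[ok] > 0)
  }, numeric(1))
  cross_idx <- which(ceac_prob >= 0.5)
  structure(
    list(draws = data.frame(iteration = seq_len(n_iterations)[ok],
                            delta_cost = dc[ok], delta_qaly = dq[ok]),
         n_iterations = n_iterations, seed = seed, n_failures = failures,
         ceac = data.frame(wtp = wtp_grid, probability = ceac_prob),
         crossover_wtp = if (length(cross_idx)) wtp_grid[min(cross_idx)]
                         else NA_real_),
    class = "psa_result"
  )
}

#' Acceptability probability at given willingness-to-pay values
#'
#' Interpolates nothing: `wtp` values must lie on the PSA grid.
#'
#' @param psa a [run_psa()] result.
#' @param wtp willingness-to-pay values ($/QALY) on the CEAC grid.
#' @return Probabilities that the intervention is cost-effective.
#' @export
ceac_probability <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  idx <- match(wtp, psa$ceac$wtp)
  if (anyNA(idx)) {
    stop("wtp value(s) not on the CEAC grid: ",
         paste(wtp[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  psa$ceac$probability[idx]
}

#' Write sensitivity-analysis outputs to CSV
#'
#' `write_tornado_csv` writes the ranked one-way results;
#' `write_psa_draws_csv` the per-iteration incremental pairs;
#' `write_ceac_csv` the acceptability curve.
#'
#' @param x a `tornado_table` / `psa_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(x, path) {
  stopifnot(inherits(x, "tornado_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_psa_draws_csv <- function(x, path) {
  stopifnot(inherits(x, "psa_result"))
  utils::write.csv(x$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_ceac_csv <- function(x, path) {
  stopifnot(inherits(x, "psa_result"))
  utils::write.csv(x$ceac, path, row.names = FALSE)
  invisible(path)
}
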