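# Kaplan-Meier estimation, pseudo-IPD reconstruction from digitized curves,
# six-family parametric fitting with AIC/BIC selection, and hazard-ratio
# adjusted survivor evaluation for the comparator arm.

#' Kaplan-Meier product-limit estimate
#'
#' @param dataset a `time`/`event` data.frame.
#' @return An object of class `km_estimate`: list with `time`, `survival`,
#'   `n_risk`, `n_event` at each distinct observed time (ties grouped).
#' @export
km_estimate <- function(dataset) {
  .validate_dataset(dataset)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = dataset)
  structure(
    list(time = fit$time, survival = fit$surv,
         n_risk = fit$n.risk, n_event = fit$n.event),
    class = "km_estimate"
  )
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' Right-continuous step-function evaluation; S(t) = 1 before the first
#' observed time.
#'
#' @param km a `km_estimate`.
#' @param t vector of times (months).
#' @return Survival probabilities at `t`.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  vapply(t, function(x) {
    i <- findInterval(x, km$time)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

#' Reconstruct pseudo patient-level data from a digitized curve
#'
#' Inverts the Kaplan-Meier estimator interval by interval. Because the
#' digitized curve carries the number at risk at every grid time, the
#' allocation is deterministic: within interval `(t_i, t_{i+1}]` the event
#' count is the integer that moves the running KM value closest to the
#' digitized survival at `t_{i+1}`, and the censoring count is whatever
#' remains of the drop in the risk table. The interval's events are spread
#' evenly over the interval's interior (so the reconstructed curve also
#' tracks the source within intervals) and its censorings are placed at the
#' right endpoint; with the censorings after the events the product-limit
#' factors telescope, so the reconstructed KM still hits the digitized
#' survival exactly at every grid point. Patients still at risk at the last
#' grid time are censored there.
#'
#' @param curve a `digitized_curve` with at least two grid points.
#' @return A pseudo-IPD `data.frame` with columns `time` and `event` whose
#'   Kaplan-Meier curve matches `curve$survival` on the grid up to integer
#'   rounding of the interval event counts.
#' @export
reconstruct_ipd <- function(curve) {
  .validate_curve(curve)
  m <- length(curve$time)
  if (m < 2L) stop("curve needs at least 2 grid points", call. = FALSE)
  if (any(diff(curve$n_risk) > 0)) {
    stop("risk-table counts increase over time", call. = FALSE)
  }
  n_cur <- curve$n_risk[1]
  s_cur <- 1
  times <- numeric(0)
  events <- integer(0)
  for (i in seq_len(m - 1L)) {
    target <- curve$survival[i + 1L]
    d <- if (s_cur > 0 && n_cur > 0) {
      round(n_cur * (1 - target / s_cur))
    } else {
      0
    }
    d <- min(max(d, 0), n_cur)
    c_i <- n_cur - d - curve$n_risk[i + 1L]
    c_i <- min(max(c_i, 0), n_cur - d)
    if (d > 0) {
      width <- curve$time[i + 1L] - curve$time[i]
      times <- c(times, curve$time[i] + width * seq_len(d) / (d + 1))
      events <- c(events, rep(1L, d))
      s_cur <- s_cur * (1 - d / n_cur)
    }
    if (c_i > 0) {
      times <- c(times, rep(curve$time[i + 1L], c_i))
      events <- c(events, rep(0L, c_i))
    }
    n_cur <- n_cur - d - c_i
  }
  if (n_cur > 0) {
    times <- c(times, rep(curve$time[m], n_cur))
    events <- c(events, rep(0L, n_cur))
  }
  data.frame(time = times, event = events)
}

#' Fit a parametric survival distribution by censored maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' `sum(event * log f(t) + (1 - event) * log S(t))` for one of the six
#' standard extrapolation families (exponential, gamma, Weibull, Gompertz,
#' log-normal, log-logistic). Fitting is delegated to
#' [flexsurv::flexsurvreg()]; AIC and BIC are recomputed from the
#' log-likelihood so the identities `AIC = 2k - 2*loglik` and
#' `BIC = k*log(n) - 2*loglik` hold exactly, with `k` the number of free
#' parameters and `n` the number of records.
#'
#' Parameterizations follow flexsurv: log-normal and log-logistic are
#' location/scale on log time; the Gompertz shape may be negative, in which
#' case the survivor function plateaus at `exp(rate/shape) > 0` instead of
#' falling to zero (an improper distribution; see [select_best()]).
#'
#' @param dataset a `time`/`event` data.frame with at least one event.
#' @param family family name (see [normalize_family()]).
#' @return An object of class `parametric_fit`: list with `family`, `params`
#'   (named, natural scale), `loglik`, `aic`, `bic`, `n`, `n_events`, and
#'   `vcov` (covariance of the estimates on flexsurv's transformed scale).
#' @export
fit_parametric <- function(dataset, family) {
  .validate_dataset(dataset)
  family <- normalize_family(family)
  if (sum(dataset$event) < 1) {
    stop("cannot fit: dataset has no observed events", call. = FALSE)
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dataset,
                          dist = .FAMILY_DIST[[family]]),
    error = function(e) {
      stop("fitting the ", family, " family failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  k <- fit$npars
  n <- nrow(dataset)
  structure(
    list(family = family, params = params, loglik = fit$loglik,
         aic = 2 * k - 2 * fit$loglik, bic = k * log(n) - 2 * fit$loglik,
         n = n, n_events = sum(dataset$event), vcov = fit$cov),
    class = "parametric_fit"
  )
}

#' Fit all six candidate families to one dataset
#'
#' @param dataset a `time`/`event` data.frame.
#' @param families families to fit; defaults to all six in the fixed
#'   tie-break order.
#' @return Named list of `parametric_fit` objects. Families whose fit fails
#'   to converge are dropped with a warning.
#' @export
fit_all_parametric <- function(dataset, families = .FAMILY_ORDER) {
  fits <- list()
  for (fam in vapply(families, normalize_family, character(1))) {
    f <- tryCatch(fit_parametric(dataset, fam), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no family could be fitted", call. = FALSE)
  fits
}

#' Select the best-fitting distribution by AIC, then BIC
#'
#' Returns the fit with minimal AIC; exact ties are broken by minimal BIC and
#' then by the fixed family order (exponential, gamma, Weibull, Gompertz,
#' log-normal, log-logistic). A Gompertz fit with negative shape has an
#' improper survivor that plateaus at `exp(rate/shape)`; such fits are
#' excluded from selection when the plateau exceeds `gompertz_plateau_floor`
#' (they cannot represent a mortal cohort over a lifetime horizon).
#'
#' @param fits list of `parametric_fit` objects on the same dataset.
#' @param gompertz_plateau_floor maximum tolerated survivor plateau for a
#'   negative-shape Gompertz fit to remain eligible.
#' @return The selected `parametric_fit`, with the full comparison table
#'   attached as attribute `"report"` (see [fit_report()]).
#' @export
select_best <- function(fits, gompertz_plateau_floor = 0.05) {
  if (!length(fits)) stop("empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "parametric_fit")))
  report <- fit_report(fits)
  eligible <- vapply(fits, function(f) {
    if (f$family == "gompertz" && f$params[["shape"]] < 0) {
      plateau <- exp(f$params[["rate"]] / f$params[["shape"]])
      plateau <= gompertz_plateau_floor
    } else {
      TRUE
    }
  }, logical(1))
  pool <- fits[eligible]
  if (!length(pool)) pool <- fits
  aics <- vapply(pool, `[[`, numeric(1), "aic")
  bics <- vapply(pool, `[[`, numeric(1), "bic")
  ord <- match(vapply(pool, `[[`, character(1), "family"), .FAMILY_ORDER)
  best <- order(aics, bics, ord)[1]
  out <- pool[[best]]
  attr(out, "report") <- report
  out
}

#' Tabulate fit diagnostics for a set of parametric fits
#'
#' One row per family with the fitted parameters, log-likelihood, AIC and
#' BIC (the structure of a supplementary model-selection table).
#'
#' @param fits list of `parametric_fit` objects.
#' @return A `data.frame` ordered by the fixed family order.
#' @export
fit_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(family = f$family,
               param1 = names(f$params)[1], value1 = unname(f$params[1]),
               param2 = ifelse(length(f$params) > 1, names(f$params)[2], NA),
               value2 = ifelse(length(f$params) > 1, unname(f$params[2]), NA),
               loglik = f$loglik, aic = f$aic, bic = f$bic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$family, .FAMILY_ORDER)), ]
  rownames(out) <- NULL
  out
}

#' Write a fit report to CSV
#'
#' @param fits list of `parametric_fit` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  utils::write.csv(fit_report(fits), path, row.names = FALSE)
  invisible(path)
}

#' Survivor function of a fitted distribution
#'
#' @param fit a `parametric_fit`.
#' @param t vector of times (months), all >= 0.
#' @return S(t) under the fitted parameters.
#' @export
fit_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  .family_survival(fit$family, fit$params, t)
}

#' Bundle a fitted reference curve with a hazard-ratio adjustment
#'
#' A `survival_model` pairs the reference arm's fitted distribution with a
#' hazard ratio of the reference arm versus the arm being modelled. The
#' comparator survivor is obtained by the proportional-hazards transform on
#' the cumulative hazard: `S(t) = S_ref(t)^(1/hr)`. With `hr = 1` the model
#' reproduces the reference curve.
#'
#' @param fit a `parametric_fit` for the reference arm.
#' @param hr_vs_reference positive hazard ratio, reference arm vs this arm
#'   (so `hr < 1`, reference better, puts this arm's curve below the
#'   reference).
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(fit, hr_vs_reference = 1) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (!is.numeric(hr_vs_reference) || length(hr_vs_reference) != 1L ||
      hr_vs_reference <= 0) {
    stop("`hr_vs_reference` must be a positive scalar", call. = FALSE)
  }
  structure(list(fit = fit, hr_vs_reference = hr_vs_reference),
            class = "survival_model")
}

#' Evaluate a hazard-ratio adjusted survivor function
#'
#' @param model a [survival_model()].
#' @param t vector of times (months), >= 0.
#' @return `S_ref(t)^(1/hr_vs_reference)`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "survival_model"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  fit_survival_at(model$fit, t)^(1 / model$hr_vs_reference)
}
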