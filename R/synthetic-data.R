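# Synthetic pseudo-IPD generation: latent event times from a named parametric
# family, uniform accrual, administrative right-censoring at a fixed data
# cutoff. Stands in for undeposited trial patient-level data so every
# downstream stage of the pipeline is testable offline.

#' Specify a synthetic survival cohort
#'
#' A cohort specification bundles everything needed to draw a reproducible
#' right-censored survival dataset for one endpoint: the latent event-time
#' distribution, the trial accrual/follow-up geometry that induces
#' administrative censoring, and a seed.
#'
#' The censoring mechanism emulates a standard single-cutoff trial: patient
#' entry times are uniform on `[0, accrual_months]`, the database lock occurs
#' `followup_months` after the first entry, so patient-level censoring time is
#' `followup_months - entry`. Set `accrual_months = 0` and
#' `followup_months = Inf` for fully observed data.
#'
#' @param n_patients integer >= 2, cohort size.
#' @param endpoint `"PFS"` or `"OS"` (label only; carried through outputs).
#' @param family distribution family name (see [normalize_family()]).
#' @param params named numeric vector of family parameters, time in months
#'   (e.g. `c(meanlog = log(4.6), sdlog = 1)` for a log-normal with median
#'   4.6 months).
#' @param accrual_months non-negative accrual duration; must be strictly less
#'   than `followup_months` so every censoring time is positive.
#' @param followup_months positive time from first entry to data cutoff;
#'   `Inf` disables censoring.
#' @param seed integer seed governing the whole draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, endpoint = c("PFS", "OS"),
                        family = "lognormal", params,
                        accrual_months = 0, followup_months = Inf,
                        seed = 1L) {
  endpoint <- match.arg(endpoint)
  family <- normalize_family(family)
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      n_patients < 2 || n_patients != floor(n_patients)) {
    stop("`n_patients` must be an integer >= 2", call. = FALSE)
  }
  params <- .validate_family_params(family, params)
  if (!is.numeric(followup_months) || length(followup_months) != 1L ||
      followup_months <= 0) {
    stop("`followup_months` must be > 0", call. = FALSE)
  }
  if (!is.numeric(accrual_months) || length(accrual_months) != 1L ||
      accrual_months < 0) {
    stop("`accrual_months` must be >= 0", call. = FALSE)
  }
  if (accrual_months >= followup_months) {
    stop("`accrual_months` must be < `followup_months` ",
         "(otherwise censoring times are not positive)", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), endpoint = endpoint,
         family = family, params = params,
         accrual_months = accrual_months, followup_months = followup_months,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate right-censored patient-level survival data
#'
#' Draw order is fixed and documented so fixtures are bit-stable: (1) the
#' `n_patients` latent event times from the specified family, (2) the
#' `n_patients` entry times, uniform on `[0, accrual_months]`. Observed time
#' is `min(latent, followup - entry)` and the event indicator is 1 iff the
#' latent time is reached before cutoff.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with columns `time` (months, > 0) and `event`
#'   (1 = event observed, 0 = right-censored), one row per patient.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  latent <- .family_rng(spec$family, spec$params, n)
  entry <- if (spec$accrual_months > 0) {
    stats::runif(n, 0, spec$accrual_months)
  } else {
    rep(0, n)
  }
  censor <- spec$followup_months - entry
  time <- pmin(latent, censor)
  event <- as.integer(latent <= censor)
  data.frame(time = time, event = event)
}

#' Analytic median of the latent event-time distribution
#'
#' Ignores censoring: this is the median of the generating family itself
#' (e.g. `exp(meanlog)` for the log-normal, `log(2)/rate` for the
#' exponential), used to calibrate cohort specifications against published
#' median survival times.
#'
#' @param spec a [cohort_spec()].
#' @return Median time in months.
#' @export
median_of <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .family_quantile(spec$family, spec$params, 0.5)
}

#' Digitize a dataset into Kaplan-Meier curve coordinates
#'
#' Evaluates the Kaplan-Meier estimator of `dataset` on a time grid and
#' tabulates the number at risk at each grid time, emulating what is read off
#' a published survival figure (at much finer risk-table resolution).
#'
#' @param dataset a `time`/`event` data.frame as from [simulate_ipd()].
#' @param grid increasing vector of months starting at 0.
#' @return An object of class `digitized_curve`: list with `time`,
#'   `survival` (non-increasing, starts at 1) and `n_risk` (non-increasing
#'   counts), all aligned with `grid`.
#' @export
digitize_km <- function(dataset, grid) {
  .validate_dataset(dataset)
  if (length(grid) < 2L || grid[1] != 0 || any(diff(grid) <= 0)) {
    stop("`grid` must be increasing and start at 0", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = dataset)
  sm <- summary(fit, times = grid, extend = TRUE)
  n_risk <- vapply(grid, function(g) sum(dataset$time >= g), integer(1))
  out <- structure(
    list(time = grid, survival = sm$surv, n_risk = n_risk),
    class = "digitized_curve"
  )
  .validate_curve(out)
  out
}

.validate_dataset <- function(dataset) {
  if (!is.data.frame(dataset) || !all(c("time", "event") %in% names(dataset))) {
    stop("dataset must be a data.frame with columns `time` and `event`",
         call. = FALSE)
  }
  if (nrow(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  if (any(dataset$time <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!all(dataset$event %in% c(0, 1))) {
    stop("`event` must be 0 or 1", call. = FALSE)
  }
  invisible(dataset)
}

.validate_curve <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  with(curve, {
    if (survival[1] != 1) stop("survival must start at 1", call. = FALSE)
    if (any(diff(survival) > 1e-12)) {
      stop("survival must be non-increasing", call. = FALSE)
    }
    if (any(diff(n_risk) > 0)) {
      stop("risk-table counts must be non-increasing", call. = FALSE)
    }
  })
  invisible(curve)
}

#' Read or write patient-level survival data as CSV
#'
#' The on-disk format is a two-column CSV with header `time,event`
#' (months, 0/1).
#'
#' @param dataset a `time`/`event` data.frame.
#' @param path file path.
#' @return `read_survival_csv` returns the validated data.frame;
#'   `write_survival_csv` returns `path` invisibly.
#' @export
write_survival_csv <- function(dataset, path) {
  .validate_dataset(dataset)
  utils::write.csv(dataset[, c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  dataset <- utils::read.csv(path)
  .validate_dataset(dataset)
  dataset[, c("time", "event")]
}

#' Write a digitized curve as a pair of CSV files
#'
#' Writes `curve.csv` (`time,survival`) and `risk.csv` (`time,n_risk`) into
#' `dir`.
#'
#' @param curve a `digitized_curve`.
#' @param dir output directory (created if missing).
#' @return Character vector of the two paths, invisibly.
#' @export
write_digitized_curve <- function(curve, dir) {
  .validate_curve(curve)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "curve.csv")
  p2 <- file.path(dir, "risk.csv")
  utils::write.csv(data.frame(time = curve$time, survival = curve$survival),
                   p1, row.names = FALSE)
  utils::write.csv(data.frame(time = curve$time, n_risk = curve$n_risk),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_digitized_curve
#' @export
read_digitized_curve <- function(dir) {
  cv <- utils::read.csv(file.path(dir, "curve.csv"))
  rk <- utils::read.csv(file.path(dir, "risk.csv"))
  out <- structure(
    list(time = cv$time, survival = cv$survival, n_risk = rk$n_risk),
    class = "digitized_curve"
  )
  .validate_curve(out)
}

# Preserve the caller's RNG state around seeded draws so package functions
# do not perturb the global random stream.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
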