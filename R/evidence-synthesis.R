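# Anchored indirect treatment comparison through a common comparator arm
# (sorafenib in the motivating application): closed-form Bucher contrast and
# an equivalent Bayesian fixed-effect normal model on the log hazard ratio.

#' A published trial treatment effect
#'
#' One hazard ratio from one trial, for an ordered comparison `arm_a` vs
#' `arm_b`, with an optional 95% confidence interval.
#'
#' @param trial_id trial label.
#' @param arm_a,arm_b strategy names; the HR is for `arm_a` relative to
#'   `arm_b` (the anchor in an indirect comparison).
#' @param endpoint `"PFS"` or `"OS"`.
#' @param hr positive hazard ratio.
#' @param ci_low,ci_high optional positive 95% interval bounds with
#'   `ci_low <= hr <= ci_high`.
#' @return An object of class `trial_effect`.
#' @export
trial_effect <- function(trial_id, arm_a, arm_b, endpoint = c("PFS", "OS"),
                         hr, ci_low = NULL, ci_high = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.numeric(hr) || hr <= 0) stop("`hr` must be > 0", call. = FALSE)
  if (!is.null(ci_low) || !is.null(ci_high)) {
    if (is.null(ci_low) || is.null(ci_high)) {
      stop("supply both `ci_low` and `ci_high` or neither", call. = FALSE)
    }
    if (ci_low <= 0 || ci_high <= 0 || ci_low > hr || hr > ci_high) {
      stop("need 0 < ci_low <= hr <= ci_high", call. = FALSE)
    }
  }
  structure(
    list(trial_id = trial_id, arm_a = arm_a, arm_b = arm_b,
         endpoint = endpoint, hr = hr, ci_low = ci_low, ci_high = ci_high),
    class = "trial_effect"
  )
}

#' Standard error of a log hazard ratio from its 95% interval
#'
#' Assumes the interval is symmetric on the log scale:
#' `SE = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param effect a [trial_effect()] with a confidence interval.
#' @return The standard error of `log(hr)`. A degenerate interval
#'   (`ci_low == ci_high`) returns 0 with a warning.
#' @export
se_from_ci <- function(effect) {
  stopifnot(inherits(effect, "trial_effect"))
  if (is.null(effect$ci_low)) {
    stop("effect carries no confidence interval; supply a standard error ",
         "or an interval", call. = FALSE)
  }
  se <- (log(effect$ci_high) - log(effect$ci_low)) / (2 * stats::qnorm(0.975))
  if (se == 0) {
    warning("degenerate interval (ci_low == ci_high): SE = 0", call. = FALSE)
  }
  se
}

.check_anchored_pair <- function(a, b) {
  stopifnot(inherits(a, "trial_effect"), inherits(b, "trial_effect"))
  if (a$endpoint != b$endpoint) {
    stop("endpoint mismatch: ", a$endpoint, " vs ", b$endpoint, call. = FALSE)
  }
  if (a$arm_b != b$arm_b) {
    stop("the two effects do not share an anchor arm (",
         a$arm_b, " vs ", b$arm_b, ")", call. = FALSE)
  }
}

.comparative_effect <- function(endpoint, hr, ci_low, ci_high, method, se) {
  structure(
    list(endpoint = endpoint, hr = hr, ci_low = ci_low, ci_high = ci_high,
         method = method, se_log_hr = se),
    class = "comparative_effect"
  )
}

#' Bucher anchored indirect comparison
#'
#' Closed-form contrast through the common anchor:
#' `log HR(A vs B) = log HR(A vs anchor) - log HR(B vs anchor)`, with the
#' variance equal to the sum of the two variances and a normal-approximation
#' 95% interval. Intervals on the inputs are optional; without them only the
#' point estimate is returned.
#'
#' @param a_vs_anchor,b_vs_anchor [trial_effect()]s sharing endpoint and
#'   anchor arm.
#' @return An object of class `comparative_effect` for A vs B.
#' @export
bucher_indirect <- function(a_vs_anchor, b_vs_anchor) {
  .check_anchored_pair(a_vs_anchor, b_vs_anchor)
  log_hr <- log(a_vs_anchor$hr) - log(b_vs_anchor$hr)
  has_ci <- !is.null(a_vs_anchor$ci_low) && !is.null(b_vs_anchor$ci_low)
  if (has_ci) {
    se <- sqrt(se_from_ci(a_vs_anchor)^2 + se_from_ci(b_vs_anchor)^2)
    z <- stats::qnorm(0.975)
    .comparative_effect(a_vs_anchor$endpoint, exp(log_hr),
                        exp(log_hr - z * se), exp(log_hr + z * se),
                        "bucher", se)
  } else {
    .comparative_effect(a_vs_anchor$endpoint, exp(log_hr), NA_real_,
                        NA_real_, "bucher", NA_real_)
  }
}

#' Bayesian anchored indirect comparison (fixed-effect)
#'
#' Fixed-effect normal model on the log hazard ratio with vague independent
#' normal priors (mean 0, sd 10) on the two basic treatment effects relative
#' to the anchor. With one trial per comparison the model is conjugate, so
#' the posterior of each basic effect is available in closed form; the
#' indirect contrast is summarized by Monte Carlo sampling of the posterior
#' difference (median and central 95% interval). In this two-trial star
#' network the posterior coincides with the Bucher result up to the prior's
#' negligible shrinkage, so the two methods must agree within Monte Carlo
#' error.
#'
#' @param a_vs_anchor,b_vs_anchor [trial_effect()]s with confidence
#'   intervals (needed for the likelihood standard errors).
#' @param n_draws number of posterior draws (warning below 1000).
#' @param seed integer seed; summaries are reproducible given the seed.
#' @param prior_sd standard deviation of the vague normal priors.
#' @return A `comparative_effect` with `method = "bayesian"`; the posterior
#'   draws of the A-vs-B hazard ratio are attached as attribute `"draws"`.
#' @export
bayesian_indirect <- function(a_vs_anchor, b_vs_anchor, n_draws = 20000L,
                              seed = 1L, prior_sd = 10) {
  .check_anchored_pair(a_vs_anchor, b_vs_anchor)
  if (is.null(a_vs_anchor$ci_low) || is.null(b_vs_anchor$ci_low)) {
    stop("both effects need confidence intervals to derive likelihood ",
         "standard errors", call. = FALSE)
  }
  if (n_draws < 1000) {
    warning("fewer than 1000 posterior draws; summaries will be noisy",
            call. = FALSE)
  }
  post <- function(eff) {
    se <- se_from_ci(eff)
    prec <- 1 / se^2 + 1 / prior_sd^2
    list(mean = (log(eff$hr) / se^2) / prec, sd = sqrt(1 / prec))
  }
  pa <- post(a_vs_anchor)
  pb <- post(b_vs_anchor)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  da <- stats::rnorm(n_draws, pa$mean, pa$sd)
  db <- stats::rnorm(n_draws, pb$mean, pb$sd)
  diff <- da - db
  qs <- stats::quantile(diff, c(0.025, 0.5, 0.975), names = FALSE)
  out <- .comparative_effect(a_vs_anchor$endpoint, exp(qs[2]), exp(qs[1]),
                             exp(qs[3]), "bayesian", stats::sd(diff))
  attr(out, "draws") <- exp(diff)
  out
}

#' Write a table of trial effects to CSV
#'
#' Columns: trial_id, arm_a, arm_b, endpoint, hr, ci_low, ci_high.
#'
#' @param effects list of [trial_effect()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_effects <- function(effects, path) {
  rows <- lapply(effects, function(e) {
    data.frame(trial_id = e$trial_id, arm_a = e$arm_a, arm_b = e$arm_b,
               endpoint = e$endpoint, hr = e$hr,
               ci_low = ifelse(is.null(e$ci_low), NA, e$ci_low),
               ci_high = ifelse(is.null(e$ci_high), NA, e$ci_high))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
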