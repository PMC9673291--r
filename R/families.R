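# Registry of the six parametric survival families used for extrapolation.
# Canonical names map onto the flexsurv/stats distribution suffixes so that
# d/p/q/r functions can be resolved generically.

.FAMILY_ORDER <- c("exponential", "gamma", "weibull", "gompertz",
                   "lognormal", "loglogistic")

.FAMILY_DIST <- c(exponential = "exp", gamma = "gamma", weibull = "weibull",
                  gompertz = "gompertz", lognormal = "lnorm",
                  loglogistic = "llogis")

.FAMILY_PARS <- list(
  exponential = "rate",
  gamma       = c("shape", "rate"),
  weibull     = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  lognormal   = c("meanlog", "sdlog"),
  loglogistic = c("shape", "scale")
)

#' Canonicalize a survival-distribution family name
#'
#' Accepts the usual aliases ("log-normal", "lnorm", "log_logistic", "exp",
#' ...) and returns one of the six canonical family names used throughout
#' the package.
#'
#' @param family character scalar naming a distribution family.
#' @return One of `"exponential"`, `"gamma"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @export
normalize_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || is.na(family)) {
    stop("`family` must be a single distribution-family name", call. = FALSE)
  }
  key <- gsub("[-_ ]", "", tolower(family))
  canon <- switch(key,
    exponential = , exp = "exponential",
    gamma = "gamma",
    weibull = "weibull",
    gompertz = "gompertz",
    lognormal = , lnorm = "lognormal",
    loglogistic = , llogis = "loglogistic",
    stop("unknown distribution family: '", family, "'", call. = FALSE)
  )
  canon
}

# Resolve the d/p/q/r function for a canonical family. Gompertz and
# log-logistic live in flexsurv; the rest are base stats.
.family_fun <- function(family, prefix) {
  dist <- .FAMILY_DIST[[family]]
  ns <- if (dist %in% c("gompertz", "llogis")) asNamespace("flexsurv")
        else asNamespace("stats")
  get(paste0(prefix, dist), envir = ns, mode = "function")
}

# Check positivity constraints on a named parameter vector.
.validate_family_params <- function(family, params) {
  wanted <- .FAMILY_PARS[[family]]
  if (is.null(names(params)) || !all(wanted %in% names(params))) {
    stop("family '", family, "' requires parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  params <- params[wanted]
  # Gompertz shape may be negative (decreasing hazard); everything else that
  # plays the role of a scale, rate, shape or sd must be strictly positive.
  positive <- setdiff(wanted, c("meanlog", if (family == "gompertz") "shape"))
  bad <- positive[params[positive] <= 0]
  if (length(bad)) {
    stop("parameter(s) ", paste(bad, collapse = ", "), " must be > 0 for the ",
         family, " family", call. = FALSE)
  }
  params
}

# Survivor function S(t) for a canonical family and named parameter vector.
.family_survival <- function(family, params, t) {
  pfun <- .family_fun(family, "p")
  args <- c(list(q = t), as.list(params), list(lower.tail = FALSE))
  do.call(pfun, args)
}

# Random event times.
.family_rng <- function(family, params, n) {
  rfun <- .family_fun(family, "r")
  do.call(rfun, c(list(n = n), as.list(params)))
}

# Analytic quantile (used for medians).
.family_quantile <- function(family, params, p) {
  qfun <- .family_fun(family, "q")
  do.call(qfun, c(list(p = p), as.list(params)))
}
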