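#' Cumulative logit development-time distribution
#'
#' Describes the spread of development (or adult senescence) times of one life
#' stage across constant temperatures.  The probability that an individual has
#' completed the stage by day `x` at temperature `i` is
#' \deqn{F(x) = 1 / (1 + \exp(-(a_i + b \log x)))}
#' with one intercept \eqn{a_i} per rearing temperature and a common slope
#' \eqn{b} shared across temperatures.  Equivalently, development times are
#' log-logistic with temperature-specific median \eqn{\exp(-a_i/b)} and a
#' common shape \eqn{b}.
#'
#' @param stage stage label, one of `"egg"`, `"larva"`, `"pupa"`, `"female"`,
#'   `"male"`.
#' @param intercepts named numeric vector of intercepts \eqn{a_i}; names are
#'   rearing temperatures in degrees Celsius.
#' @param slope common slope \eqn{b > 0} (dimensionless).
#' @param aic,r2 goodness-of-fit indicators of the fit that produced the
#'   parameters (optional).
#' @param flags character vector of fitting flags (e.g. `"degenerate"`).
#' @return an object of class `dev_time_dist`.
#' @seealso [eval_dev_time_cdf()], [median_dev_time()],
#'   [fit_dev_time_distribution()]
#' @export
dev_time_dist <- function(stage, intercepts, slope, aic = NA_real_,
                          r2 = NA_real_, flags = character()) {
  stage <- match.arg(stage, c("egg", "larva", "pupa", "female", "male"))
  if (is.null(names(intercepts)) || any(!nzchar(names(intercepts))))
    stop("'intercepts' must be named by temperature (degrees C)")
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0)
    stop("'slope' must be a single positive number")
  structure(
    list(stage = stage, intercepts = intercepts, slope = slope,
         aic = aic, r2 = r2, flags = flags),
    class = "dev_time_dist")
}

#' @export
print.dev_time_dist <- function(x, ...) {
  cat("Cumulative logit development-time distribution --", x$stage, "\n")
  cat("  common slope b =", format(x$slope), "\n")
  cat("  medians (days) by temperature:\n")
  meds <- exp(-x$intercepts / x$slope)
  print(round(stats::setNames(meds, paste0(names(x$intercepts), "C")), 3))
  if (!is.na(x$aic)) cat("  AIC =", format(x$aic), " R2 =", format(x$r2), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.dt_intercept <- function(dist, temperature) {
  key <- match(as.character(temperature), names(dist$intercepts))
  if (is.na(key)) {
    # tolerate numeric formatting differences ("25" vs "25.0")
    temps <- suppressWarnings(as.numeric(names(dist$intercepts)))
    key <- which(abs(temps - temperature) < 1e-8)[1]
  }
  if (is.na(key))
    stop(sprintf(
      "no intercept fitted at %s degrees C for stage '%s'; available: %s",
      format(temperature), dist$stage,
      paste(names(dist$intercepts), collapse = ", ")))
  unname(dist$intercepts[key])
}

#' Evaluate the cumulative development-time distribution
#'
#' @param dist a [dev_time_dist()] object.
#' @param temperature rearing temperature (degrees C); must be one of the
#'   fitted temperatures.
#' @param x time in days (vectorized); must be positive.
#' @return probability of having completed the stage by day `x`.
#' @export
eval_dev_time_cdf <- function(dist, temperature, x) {
  stopifnot(inherits(dist, "dev_time_dist"))
  a <- .dt_intercept(dist, temperature)
  if (any(x <= 0)) stop("'x' must be positive (days)")
  stats::plogis(a + dist$slope * log(x))
}

#' Median development time implied by the logit distribution
#'
#' The day at which the cumulative logit distribution reaches one half,
#' `exp(-a_i / b)`.
#'
#' @inheritParams eval_dev_time_cdf
#' @return median time in days.
#' @export
median_dev_time <- function(dist, temperature) {
  stopifnot(inherits(dist, "dev_time_dist"))
  a <- .dt_intercept(dist, temperature)
  exp(-a / dist$slope)
}

# maximum slope used when the observed times are a point mass and the logit
# slope is unidentifiable
.DT_SLOPE_CAP <- 60

#' Fit the cumulative logit development-time distribution
#'
#' Maximizes the binomial likelihood of the per-day cumulative completion
#' fractions against the logit curve, with one intercept per temperature and a
#' common log-time slope, via [stats::glm()].  Only individuals that completed
#' the stage contribute.
#'
#' When every temperature has all completions on a single day the slope is
#' unidentifiable; the fit is flagged `"degenerate"` and returned with the
#' slope capped at `60` and intercepts placed so that the median equals the
#' observed day.
#'
#' @param data a data frame of cohort records with columns `stage`,
#'   `temperature_C`, `individual_id`, `outcome`
#'   (`completed`/`died`/`censored`) and `event_day`, or a `cohort_data`
#'   object (see [read_cohort_csv()]).
#' @param stage stage to fit; defaults to the single stage present.
#' @return a [dev_time_dist()] object with AIC and pseudo-R2 (squared
#'   correlation of observed and fitted cumulative fractions).
#' @export
fit_dev_time_distribution <- function(data, stage = NULL) {
  rec <- if (inherits(data, "cohort_data")) data$records else data
  if (!is.null(stage)) rec <- rec[rec$stage == stage, , drop = FALSE]
  if (is.null(stage)) {
    stage <- unique(rec$stage)
    if (length(stage) != 1L)
      stop("records contain several stages; give 'stage'")
  }
  rec <- rec[rec$outcome == "completed", , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty cohort: no completed individuals")
  if (any(rec$event_day < 1)) stop("event_day must be >= 1")

  temps <- sort(unique(rec$temperature_C))
  # per-temperature cumulative completion table
  tab <- do.call(rbind, lapply(temps, function(tt) {
    d <- rec$event_day[rec$temperature_C == tt]
    days <- sort(unique(d))
    data.frame(temperature_C = tt, day = days,
               k = cumsum(tabulate(match(d, days))), n = length(d))
  }))

  degenerate <- all(vapply(split(tab$day, tab$temperature_C), length,
                           1L) == 1L)
  if (degenerate) {
    b <- .DT_SLOPE_CAP
    a <- -b * log(tab$day)
    names(a) <- as.character(tab$temperature_C)
    return(dev_time_dist(stage, a, b, flags = "degenerate"))
  }

  tab$ftemp <- factor(tab$temperature_C)
  fit <- stats::glm(cbind(k, n - k) ~ 0 + ftemp + log(day),
                    family = stats::binomial(), data = tab)
  cf <- stats::coef(fit)
  b <- unname(cf["log(day)"])
  flags <- character()
  if (!is.finite(b) || b > .DT_SLOPE_CAP) {
    b <- .DT_SLOPE_CAP
    flags <- c(flags, "slope_capped")
  }
  if (b <= 0) stop("fitted slope is non-positive; data are not cumulative in time")
  a <- cf[grepl("^ftemp", names(cf))]
  names(a) <- levels(tab$ftemp)
  obs <- tab$k / tab$n
  r2 <- stats::cor(obs, stats::fitted(fit))^2
  dev_time_dist(stage, a, b, aic = stats::AIC(fit), r2 = r2, flags = flags)
}
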