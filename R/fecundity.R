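#' Temperature-dependent total fecundity model
#'
#' Lifetime egg production per female as a function of constant temperature.
#' The default `exp_quadratic` form is the exponential polynomial
#' \deqn{f(T) = \exp(a + bT + cT^2)}
#' which, with `c < 0`, peaks at `T = -b/(2c)`.  An alternative
#' `one_minus_exp_cubic` form `1 - exp(-(aT + bT^2 + cT^3))` is retained for
#' completeness; note it is bounded in `[0, 1)` and therefore only usable as a
#' normalized fecundity index, never as an egg count.
#'
#' @param form `"exp_quadratic"` (default) or `"one_minus_exp_cubic"`.
#' @param a,b,c polynomial coefficients (powers of temperature in degrees C).
#' @param aic,r2 goodness-of-fit indicators.
#' @return an object of class `fecundity_model`.
#' @export
fecundity_model <- function(form = c("exp_quadratic", "one_minus_exp_cubic"),
                            a, b, c, aic = NA_real_, r2 = NA_real_) {
  form <- match.arg(form)
  structure(list(form = form, a = a, b = b, c = c, aic = aic, r2 = r2),
            class = "fecundity_model")
}

#' Evaluate total lifetime fecundity at a temperature
#'
#' @param model a [fecundity_model()].
#' @param temperature degrees C (vectorized).
#' @return eggs per female (`exp_quadratic`) or a bounded index in `[0, 1)`
#'   (`one_minus_exp_cubic`); always nonnegative.
#' @export
eval_total_fecundity <- function(model, temperature) {
  stopifnot(inherits(model, "fecundity_model"))
  Tc <- temperature
  switch(model$form,
    exp_quadratic = exp(model$a + model$b * Tc + model$c * Tc^2),
    one_minus_exp_cubic =
      pmax(1 - exp(-(model$a * Tc + model$b * Tc^2 + model$c * Tc^3)), 0))
}

#' @export
print.fecundity_model <- function(x, ...) {
  cat("Total fecundity model (", x$form, ")\n", sep = "")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g\n", x$a, x$b, x$c))
  if (x$form == "exp_quadratic" && x$c < 0)
    cat(sprintf("  peak at T = %.2f C (f = %.1f eggs/female)\n",
                -x$b / (2 * x$c),
                exp(x$a - x$b^2 / (4 * x$c) + x$b * -x$b / (2 * x$c) * 0)))
  invisible(x)
}

#' Fit the exponential-quadratic total fecundity curve
#'
#' Ordinary least squares of `log(f)` on `T` and `T^2` (exact maximum
#' likelihood under multiplicative lognormal error), refined on the raw scale
#' with [minpack.lm::nlsLM()].  Temperatures with zero observed fecundity are
#' excluded from the log fit (the curve approaches but never reaches zero).
#'
#' @param observed named numeric vector (names = temperatures, degrees C) or
#'   a data frame with columns `temperature_C` and `fecundity` of mean total
#'   eggs per female.
#' @return a [fecundity_model()] of form `exp_quadratic` with AIC and R2.
#' @export
fit_total_fecundity <- function(observed) {
  tab <- .rate_table(observed,
                     value = if (is.data.frame(observed) &&
                                 "fecundity" %in% names(observed))
                       "fecundity" else "rate")
  tab <- tab[tab$value > 0, , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 temperatures with nonzero fecundity")
  Tc <- tab$temperature_C
  y <- tab$value
  lmfit <- stats::lm(log(y) ~ Tc + I(Tc^2))
  st <- as.list(stats::setNames(stats::coef(lmfit), c("a", "b", "c")))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(a + b * Tc + c * Tc^2), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- st
    aic <- stats::AIC(lmfit)
    r2 <- summary(lmfit)$r.squared
  } else {
    cf <- as.list(stats::coef(fit))
    aic <- stats::AIC(fit)
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  }
  fecundity_model("exp_quadratic", cf$a, cf$b, cf$c, aic = aic, r2 = r2)
}

#' Gamma age-specific oviposition schedule
#'
#' The cumulative fraction of a female's lifetime eggs laid by normalized
#' (physiological) age `X = age in days / mean adult survival time` follows a
#' Gamma cumulative distribution with shape `a` and *rate* `b`:
#' `G(X) = pgamma(X, shape = a, rate = b)`.
#'
#' @param shape Gamma shape parameter `a > 0`.
#' @param rate Gamma rate parameter `b > 0` (per unit normalized age).
#' @param aic,r2 goodness-of-fit indicators.
#' @return an object of class `oviposition_model`.
#' @export
oviposition_model <- function(shape, rate, aic = NA_real_, r2 = NA_real_) {
  if (shape <= 0 || rate <= 0) stop("'shape' and 'rate' must be positive")
  structure(list(shape = shape, rate = rate, aic = aic, r2 = r2),
            class = "oviposition_model")
}

#' Cumulative oviposition fraction at a normalized age
#'
#' @param model an [oviposition_model()].
#' @param X normalized female age (age in days / mean survival time),
#'   nonnegative (vectorized).
#' @return cumulative fraction of lifetime eggs laid by age `X`.
#' @export
eval_oviposition_cdf <- function(model, X) {
  stopifnot(inherits(model, "oviposition_model"))
  if (any(X < 0)) stop("'X' must be nonnegative")
  stats::pgamma(X, shape = model$shape, rate = model$rate)
}

#' Normalized age at which half the lifetime eggs are laid
#'
#' Numerically inverts the cumulative oviposition schedule at one half by
#' root bracketing on [eval_oviposition_cdf()].
#'
#' @param model an [oviposition_model()].
#' @return the median normalized oviposition age.
#' @export
median_oviposition_age <- function(model) {
  stats::uniroot(function(X) eval_oviposition_cdf(model, X) - 0.5,
                 lower = 1e-9, upper = 1e3, tol = 1e-10)$root
}

#' Fit the Gamma oviposition schedule
#'
#' Nonlinear least squares of observed cumulative oviposition fractions
#' against the Gamma CDF via [minpack.lm::nlsLM()], seeded by moment matching
#' of the egg-weighted age distribution.
#'
#' @param X normalized ages.
#' @param cumfrac observed cumulative fractions in `[0, 1]` at those ages.
#' @return an [oviposition_model()].
#' @export
fit_oviposition <- function(X, cumfrac) {
  stopifnot(length(X) == length(cumfrac), all(X >= 0),
            all(cumfrac >= 0 & cumfrac <= 1.000001))
  # moment seed from the implied density
  dens <- diff(c(0, cumfrac))
  dens[dens < 0] <- 0
  mu <- sum(X * dens) / max(sum(dens), 1e-12)
  v <- sum((X - mu)^2 * dens) / max(sum(dens), 1e-12)
  sh0 <- if (v > 0) max(mu^2 / v, 0.5) else 2
  rt0 <- if (mu > 0) sh0 / mu else 1
  fit <- minpack.lm::nlsLM(
    cumfrac ~ stats::pgamma(X, shape = shape, rate = rate),
    start = list(shape = sh0, rate = rt0),
    lower = c(shape = 1e-3, rate = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- as.list(stats::coef(fit))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((cumfrac - mean(cumfrac))^2)
  oviposition_model(cf$shape, cf$rate, aic = stats::AIC(fit), r2 = r2)
}

#' Rank candidate sub-models by goodness of fit
#'
#' Orders candidates by ascending AIC, breaking ties by descending R2.  The
#' full ranking is returned; no candidate is dropped.
#'
#' @param candidates a named list of fitted sub-model objects, each carrying
#'   `aic` and `r2` elements.
#' @return a data frame with columns `rank`, `model`, `aic`, `r2`, plus the
#'   reordered candidate list as attribute `"models"`.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0L) stop("empty candidate list")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  aic <- vapply(candidates, function(m) as.numeric(m$aic), 1)
  r2 <- vapply(candidates, function(m) as.numeric(m$r2), 1)
  ord <- order(aic, -r2)
  out <- data.frame(rank = seq_along(ord), model = names(candidates)[ord],
                    aic = aic[ord], r2 = r2[ord], row.names = NULL)
  attr(out, "models") <- candidates[ord]
  out
}
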