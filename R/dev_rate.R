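#' @title Modified four-parameter Sharpe-DeMichele development-rate model
#'
#' @description Enzyme-kinetics model of poikilotherm development rate versus
#' absolute temperature, in the four-parameter variant that retains
#' high-temperature enzyme inactivation only:
#' \deqn{r(T) = p \frac{T}{T_o}
#'   \exp\left[\frac{\Delta H_a}{R}\left(\frac{1}{T_o}-\frac{1}{T}\right)\right]
#'   \Big/ \left(1 + \exp\left[\frac{\Delta H_h}{R}
#'   \left(\frac{1}{T_h}-\frac{1}{T}\right)\right]\right)}
#' with `T` in Kelvin, `p` the rate (1/day) at the reference optimum `To`
#' assuming no inactivation, `dHa` the enthalpy of activation (cal/mol), `dHh`
#' the high-temperature inactivation enthalpy (cal/mol), `Th` the temperature
#' (K) at which the rate-controlling enzyme is half inactivated, and the gas
#' constant `R = 1.987` cal/(K mol).
#'
#' @param stage stage label.
#' @param p rate per day at `To` assuming no inactivation; `> 0`.
#' @param To reference optimum temperature, Kelvin.
#' @param dHa enthalpy of activation, cal/mol.
#' @param dHh high-temperature inactivation enthalpy, cal/mol.
#' @param Th half-inactivation temperature, Kelvin; must exceed `To`.
#' @param aic,r2 goodness-of-fit indicators.
#' @param flags character fitting flags (e.g. `"Th_at_bound"`).
#' @return an object of class `dev_rate_model`.
#' @export
dev_rate_model <- function(stage, p, To, dHa, dHh, Th, aic = NA_real_,
                           r2 = NA_real_, flags = character()) {
  if (p <= 0) stop("'p' must be positive")
  if (To >= Th) stop("'To' must be below 'Th'")
  structure(
    list(stage = stage, p = p, To = To, dHa = dHa, dHh = dHh, Th = Th,
         aic = aic, r2 = r2, flags = flags),
    class = "dev_rate_model")
}

#' Universal gas constant used throughout, cal/(K mol)
#' @export
R_GAS <- 1.987

.sharpe_demichele <- function(TK, p, To, dHa, dHh, Th) {
  num <- p * (TK / To) * exp(dHa / R_GAS * (1 / To - 1 / TK))
  den <- 1 + exp(dHh / R_GAS * (1 / Th - 1 / TK))
  pmax(num / den, 0)
}

#' Evaluate the Sharpe-DeMichele development rate
#'
#' @param model a [dev_rate_model()].
#' @param temperature temperature in degrees Celsius (vectorized); converted
#'   internally to Kelvin.
#' @return development (or senescence) rate per day, nonnegative.
#' @export
eval_development_rate <- function(model, temperature) {
  stopifnot(inherits(model, "dev_rate_model"))
  TK <- temperature + 273.15
  if (any(TK <= 0)) stop("temperature below absolute zero")
  .sharpe_demichele(TK, model$p, model$To, model$dHa, model$dHh, model$Th)
}

#' @export
print.dev_rate_model <- function(x, ...) {
  cat("Sharpe-DeMichele development-rate model --", x$stage, "\n")
  cat(sprintf("  p = %.4g /day, To = %.2f K, dHa = %.4g, dHh = %.4g, Th = %.2f K\n",
              x$p, x$To, x$dHa, x$dHh, x$Th))
  if (!is.na(x$aic)) cat("  AIC =", format(x$aic), " R2 =", format(x$r2), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.rate_table <- function(rates, value = "rate") {
  if (is.data.frame(rates)) {
    tc <- intersect(c("temperature_C", "temperature"), names(rates))[1]
    data.frame(temperature_C = rates[[tc]], value = rates[[value]])
  } else {
    data.frame(temperature_C = as.numeric(names(rates)),
               value = as.numeric(rates))
  }
}

#' Fit the Sharpe-DeMichele model to observed mean rates
#'
#' Nonlinear least squares on the rate scale via [minpack.lm::nlsLM()], with a
#' multi-start grid over the enthalpy parameters (1e3 to 1e6 cal/mol on a log
#' grid) and `To`/`Th` seeded from the temperature of the fastest observed
#' rate and the highest tested temperature.  `Th` is bounded above at the
#' highest tested temperature plus 20 K; a fit pinned at that bound (which
#' happens when the rates never decline, leaving the inactivation branch
#' unidentifiable) is flagged `"Th_at_bound"`.
#'
#' Because `p`, `To` and `dHa` enter the curve only through the combination
#' `p exp(dHa/(R To))/To`, the reported `To` is a convention, not a free
#' parameter: the fitter renormalizes so that `To` is the temperature at
#' which the fitted curve attains its maximum (capped just below `Th`), with
#' `p` adjusted so the curve itself is unchanged.
#'
#' @param rates named numeric vector (names = temperatures, degrees C) or a
#'   data frame with columns `temperature_C` and `rate` of observed mean
#'   rates (1/day).
#' @param stage stage label stored in the result.
#' @return a [dev_rate_model()] with AIC and R2.
#' @export
fit_development_rate <- function(rates, stage = "stage") {
  tab <- .rate_table(rates)
  if (nrow(tab) < 5L)
    stop("need at least 5 temperature points to fit 4 parameters")
  TK <- tab$temperature_C + 273.15
  y <- tab$value
  To0 <- TK[which.max(y)]
  Th_hi <- max(TK) + 20
  lower <- c(p = 1e-8, To = min(TK) - 20, dHa = 1e2, dHh = 1e3,
             Th = min(TK))
  upper <- c(p = 10, To = Th_hi - 1e-3, dHa = 1e7, dHh = 5e7, Th = Th_hi)

  # Arrhenius seed: below the optimum log r is near-linear in 1/T with
  # slope -dHa/R, giving a data-driven enthalpy start
  pos <- y > 0
  dHa_arr <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ I(1 / TK[pos])))[2]
    min(max(-sl * R_GAS, 1e3), 1e6)
  } else 1e4
  starts <- expand.grid(
    dHa = unique(c(dHa_arr, 1e3, 1e4, 1e5, 1e6)),
    dHh = c(1e4, 1e5, 1e6),
    To = unique(c(To0, stats::median(TK))),
    Th = unique(c(max(TK) + 2, Th_hi - 5)))
  starts <- lapply(seq_len(nrow(starts)), function(k)
    c(p = max(y), To = min(starts$To[k], starts$Th[k] - 1),
      dHa = starts$dHa[k], dHh = starts$dHh[k], Th = starts$Th[k]))
  best <- .lm_multistart(
    function(par) y - .sharpe_demichele(TK, par["p"], par["To"], par["dHa"],
                                        par["dHh"], par["Th"]),
    starts, lower, upper)
  if (is.null(best))
    stop("Sharpe-DeMichele fit did not converge from any start")
  cf <- as.list(best$par)
  flags <- character()
  # the inactivation branch is unidentifiable when no decline is observed:
  # either Th pinned at its bound or the curve still rising at the hottest
  # tested temperature
  dense <- seq(min(TK) - 5, max(cf$Th + 10, max(TK) + 10), by = 0.01)
  argmax_K <- dense[which.max(
    .sharpe_demichele(dense, cf$p, cf$To, cf$dHa, cf$dHh, cf$Th))]
  if (cf$Th > Th_hi - 0.5 || argmax_K >= max(TK) - 1e-9)
    flags <- c(flags, "Th_at_bound")
  # p, To and dHa enter the curve only through p exp(dHa/R/To)/To, so To is
  # a reporting convention: renormalize to To = the curve argmax (p
  # recomputed in log space; the fitted curve is unchanged)
  log_c <- log(cf$p) + cf$dHa / (R_GAS * cf$To) - log(cf$To)
  grid <- seq(273.15, max(cf$Th + 10, max(TK) + 10), by = 0.01)
  To_new <- min(grid[which.max(
    .sharpe_demichele(grid, cf$p, cf$To, cf$dHa, cf$dHh, cf$Th))],
    cf$Th - 0.5)
  cf$p <- exp(log_c + log(To_new) - cf$dHa / (R_GAS * To_new))
  cf$To <- To_new
  r2 <- 1 - best$ss / sum((y - mean(y))^2)
  dev_rate_model(stage, cf$p, cf$To, cf$dHa, cf$dHh, cf$Th,
                 aic = .lm_aic(best$ss, length(y), 5L), r2 = r2,
                 flags = flags)
}

# Levenberg-Marquardt least squares over a list of starts; returns the best
# converged solution (par, ss) or NULL.  Raw nls.lm is used rather than the
# nls-object interface so rank-deficient Jacobians at the optimum (the
# classic ridge of this model family) do not abort an otherwise good fit.
.lm_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL; best_ss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:5) {
      ss <- sum(fit$fvec^2)
      if (ss < best_ss) { best <- list(par = fit$par, ss = ss); best_ss <- ss }
    }
  }
  best
}

# Gaussian AIC for a least-squares fit with k mean parameters
.lm_aic <- function(ss, n, k)
  n * (log(2 * pi * ss / n) + 1) + 2 * (k + 1)
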