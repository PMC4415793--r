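#' Wang temperature-mortality model
#'
#' Symmetric U-shaped curve giving the total mortality of one immature stage
#' as a function of constant temperature:
#' \deqn{m(T) = 1 - \exp\left\{-H\left[1 + e^{-(T-T_{opt})/B}\right]
#'   \left[1 + e^{-(T_{opt}-T)/B}\right]\right\}}
#' Mortality is minimized at the survival optimum `Topt` where it equals
#' `1 - exp(-4 H)` exactly, and rises symmetrically on either side with
#' spread `B`.
#'
#' @param stage stage label.
#' @param Topt optimum temperature for cohort survival, degrees C.
#' @param B spread parameter, degrees C, `> 0`.
#' @param H mortality intensity, dimensionless, `>= 0`.
#' @param aic,r2 goodness-of-fit indicators.
#' @param flags character fitting flags.
#' @return an object of class `mortality_model`.
#' @export
mortality_model <- function(stage, Topt, B, H, aic = NA_real_, r2 = NA_real_,
                            flags = character()) {
  if (B <= 0) stop("'B' must be positive")
  if (H < 0) stop("'H' must be nonnegative")
  structure(
    list(stage = stage, Topt = Topt, B = B, H = H, aic = aic, r2 = r2,
         flags = flags),
    class = "mortality_model")
}

#' Evaluate stage mortality at a temperature
#'
#' @param model a [mortality_model()].
#' @param temperature degrees C (vectorized).
#' @return mortality probability in `[0, 1]`.
#' @export
eval_mortality <- function(model, temperature) {
  stopifnot(inherits(model, "mortality_model"))
  if (model$H == 0) return(rep(0, length(temperature)))
  z <- (temperature - model$Topt) / model$B
  arg <- model$H * (1 + exp(-z)) * (1 + exp(z))
  m <- 1 - exp(-arg)
  m[is.infinite(arg)] <- 1  # exp overflow far from Topt
  pmin(pmax(m, 0), 1)
}

#' @export
print.mortality_model <- function(x, ...) {
  cat("Wang temperature-mortality model --", x$stage, "\n")
  cat(sprintf("  Topt = %.2f C, B = %.3g C, H = %.4g; m(Topt) = %.4f\n",
              x$Topt, x$B, x$H, 1 - exp(-4 * x$H)))
  if (!is.na(x$aic)) cat("  AIC =", format(x$aic), " R2 =", format(x$r2), "\n")
  invisible(x)
}

#' Fit the Wang mortality model
#'
#' Nonlinear least squares on observed per-temperature mortality fractions
#' via [minpack.lm::nlsLM()] with a small multi-start over the spread `B`.
#' `H` is constrained nonnegative.  Uniformly zero mortalities return the
#' exact boundary solution `H = 0`, flagged `"flat"`.
#'
#' @param observed named numeric vector (names = temperatures, degrees C) or
#'   data frame with columns `temperature_C` and `mortality` of observed
#'   stage mortality fractions in `[0, 1]`.
#' @param stage stage label stored in the result.
#' @return a [mortality_model()] with AIC and R2.
#' @export
fit_mortality <- function(observed, stage = "stage") {
  tab <- .rate_table(observed,
                     value = if (is.data.frame(observed) &&
                                 "mortality" %in% names(observed))
                       "mortality" else "rate")
  if (nrow(tab) < 4L) stop("need at least 4 temperature points")
  Tc <- tab$temperature_C
  y <- pmin(pmax(tab$value, 0), 1)
  if (all(y == 0))
    return(mortality_model(stage, mean(range(Tc)), 1, 0, flags = "flat"))

  Topt0 <- Tc[which.min(y)]
  H0 <- max(-log(1 - min(y)) / 4, 1e-4)
  wang <- function(Tc, Topt, B, H) {
    z <- (Tc - Topt) / B
    m <- 1 - exp(-H * (1 + exp(-z)) * (1 + exp(z)))
    m[!is.finite(m)] <- 1
    pmin(pmax(m, 0), 1)
  }
  starts <- lapply(c(1, 2, 4, 8), function(B0)
    c(Topt = Topt0, B = B0, H = H0))
  best <- .lm_multistart(
    function(par) y - wang(Tc, par["Topt"], par["B"], par["H"]),
    starts,
    lower = c(Topt = min(Tc) - 10, B = 0.05, H = 0),
    upper = c(Topt = max(Tc) + 10, B = 50, H = 10))
  if (is.null(best)) stop("Wang mortality fit did not converge")
  cf <- as.list(best$par)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$ss / sst else NA_real_
  mortality_model(stage, cf$Topt, cf$B, cf$H,
                  aic = .lm_aic(best$ss, length(y), 3L), r2 = r2)
}
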