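#' @title Synthetic data generators
#'
#' @description Generators that emit cohort observations, daily weather and
#' gridded monthly climatologies with exactly the statistical structure the
#' fitting and simulation machinery assumes: development times are
#' log-logistic (the cumulative logit law), survival is Bernoulli with the
#' Wang stage mortality, lifetime fecundity follows the exponential
#' quadratic curve, and daily egg laying apportions the total by the Gamma
#' oviposition schedule.  Every generator is deterministic under its seed.
#'
#' @name synthetic_data
NULL

.draw_dev_days <- function(n, a, b) {
  # inverse-CDF draw from F(x) = plogis(a + b log x), recorded in whole days
  u <- stats::runif(n)
  pmax(ceiling(exp((stats::qlogis(u) - a) / b)), 1L)
}

#' Generate cohort observations from a known phenology model
#'
#' Per temperature: `n["egg"]`, `n["larva"]`, `n["pupa"]` immatures whose
#' survival is Bernoulli with the Wang mortality and whose development times
#' are inverse-CDF draws from the logit distribution rounded up to whole
#' days (individuals that die get a uniformly placed death day within their
#' drawn development time); `n["adult"]` females and as many males with
#' senescence times from the adult logit laws; per-female lifetime egg
#' totals drawn Poisson around the fecundity curve (or negative binomial
#' when `dispersion > 1`, with variance inflated by that factor) and
#' allocated across adult days by Gamma-schedule increments on the
#' normalized age grid.
#'
#' @param phenology the true [phenology_model()]; every requested
#'   temperature must have logit intercepts.
#' @param temperatures rearing temperatures, degrees C.
#' @param n named cohort sizes: `egg`, `larva`, `pupa`, `adult` (per sex).
#'   Defaults mirror a typical constant-temperature rearing design
#'   (400/200/100/30).
#' @param dispersion egg-count overdispersion factor `>= 1` (1 = Poisson).
#' @param seed integer seed, recorded in the output.
#' @return a `cohort_data` object with attributes `seed` and `spec`.
#' @export
generate_cohort <- function(phenology, temperatures,
                            n = c(egg = 400, larva = 200, pupa = 100,
                                  adult = 30),
                            dispersion = 1, seed = 1) {
  stopifnot(all(n >= 1), dispersion >= 1)
  set.seed(seed)
  recs <- list()
  eggs <- list()
  for (tc in temperatures) {
    for (s in .STAGES) {
      a <- .dt_intercept(phenology$dev_time[[s]], tc)
      b <- phenology$dev_time[[s]]$slope
      m <- eval_mortality(phenology$mortality[[s]], tc)
      ns <- n[[s]]
      dev <- .draw_dev_days(ns, a, b)
      died <- stats::runif(ns) < m
      day <- ifelse(died, pmax(ceiling(stats::runif(ns) * dev), 1L), dev)
      recs[[length(recs) + 1L]] <- data.frame(
        stage = s, temperature_C = tc,
        individual_id = paste0(s, "_", tc, "_", seq_len(ns)),
        outcome = ifelse(died, "died", "completed"), event_day = day)
    }
    for (s in c("female", "male")) {
      a <- .dt_intercept(phenology$dev_time[[s]], tc)
      b <- phenology$dev_time[[s]]$slope
      ns <- n[["adult"]]
      life <- .draw_dev_days(ns, a, b)
      ids <- paste0(s, "_", tc, "_", seq_len(ns))
      recs[[length(recs) + 1L]] <- data.frame(
        stage = s, temperature_C = tc, individual_id = ids,
        outcome = "completed", event_day = life)
      if (s == "female") {
        fT <- eval_total_fecundity(phenology$fecundity, tc)
        L <- median_dev_time(phenology$dev_time$female, tc)
        for (i in seq_len(ns)) {
          tot <- if (dispersion > 1)
            stats::rnbinom(1, size = fT / (dispersion - 1), mu = fT)
          else stats::rpois(1, fT)
          if (tot == 0) next
          days <- seq_len(life[i])
          p <- diff(c(0, eval_oviposition_cdf(phenology$oviposition,
                                              days / L)))
          if (sum(p) <= 0) next
          laid <- as.vector(stats::rmultinom(1, tot, p / sum(p)))
          keep <- laid > 0
          if (any(keep))
            eggs[[length(eggs) + 1L]] <- data.frame(
              temperature_C = tc, female_id = ids[i],
              age_day = days[keep], eggs = laid[keep])
        }
      }
    }
  }
  out <- cohort_data(do.call(rbind, recs),
                     if (length(eggs)) do.call(rbind, eggs) else NULL)
  attr(out, "seed") <- seed
  attr(out, "spec") <- list(temperatures = temperatures, n = n,
                            dispersion = dispersion)
  out
}

#' Generate a synthetic daily weather series
#'
#' A sinusoidal annual cycle with Gaussian day-to-day noise, emulating a
#' semi-arid station year: daily midpoint
#' `year_mean + amplitude sin(2 pi (d - 110)/365)`, maxima and minima offset
#' by half the diurnal range, `tmin <= tmax` enforced.
#'
#' @param year_mean annual mean temperature, degrees C.
#' @param amplitude seasonal half-range of the daily midpoint, degrees C.
#' @param diurnal_range mean daily max-min spread, degrees C.
#' @param noise_sd day-to-day Gaussian noise SD, degrees C.
#' @param days series length (default 365).
#' @param seed integer seed.
#' @return a [temperature_series()] with attribute `seed`.
#' @export
generate_weather <- function(year_mean = 25, amplitude = 8,
                             diurnal_range = 11, noise_sd = 1.5,
                             days = 365, seed = 1) {
  stopifnot(amplitude >= 0, diurnal_range >= 0, noise_sd >= 0)
  set.seed(seed)
  d <- seq_len(days)
  mid <- year_mean + amplitude * sin(2 * pi * (d - 110) / 365)
  tmax <- mid + diurnal_range / 2 + stats::rnorm(days, 0, noise_sd)
  tmin <- mid - diurnal_range / 2 + stats::rnorm(days, 0, noise_sd)
  tmin <- pmin(tmin, tmax)
  out <- temperature_series(d, tmin, tmax)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic gridded monthly climatology
#'
#' Per cell: a seasonal cosine cycle evaluated at month midpoints plus a
#' linear south-north gradient (bottom rows warmest, total span
#' `south_north_gradient`), with optional cell-level Gaussian noise.
#' Optionally surrounds the grid with a one-cell nodata border for mask
#' testing.
#'
#' @param nrows,ncols grid dimensions (data cells).
#' @param south_north_gradient total temperature span from the north (top)
#'   row to the south (bottom) row, degrees C.
#' @param base_mean,amplitude,diurnal_range as in [generate_weather()].
#' @param noise_sd per-cell Gaussian noise SD (default 0).
#' @param nodata_border add a one-cell `NA` frame around the grid.
#' @param cellsize,xll,yll geometry of the output grids.
#' @param seed integer seed.
#' @return a `climate_stack` with attribute `seed`.
#' @export
generate_climate_raster <- function(nrows, ncols, south_north_gradient = 5,
                                    base_mean = 25, amplitude = 8,
                                    diurnal_range = 11, noise_sd = 0,
                                    nodata_border = FALSE, cellsize = 1,
                                    xll = 0, yll = 0, seed = 1) {
  stopifnot(nrows >= 1, ncols >= 1)
  set.seed(seed)
  mid_season <- base_mean +
    amplitude * sin(2 * pi * (.MONTH_MID - 110) / 365)
  row_offset <- if (nrows > 1)
    south_north_gradient * (seq_len(nrows) - 1) / (nrows - 1)
  else rep(0, 1)
  tmin <- array(NA_real_, c(nrows, ncols, 12))
  tmax <- array(NA_real_, c(nrows, ncols, 12))
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      eps <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
      mid <- mid_season + row_offset[i] + eps
      tmin[i, j, ] <- mid - diurnal_range / 2
      tmax[i, j, ] <- mid + diurnal_range / 2
    }
  }
  if (nodata_border) {
    pad <- function(a) {
      out <- array(NA_real_, c(nrows + 2, ncols + 2, 12))
      out[2:(nrows + 1), 2:(ncols + 1), ] <- a
      out
    }
    tmin <- pad(tmin); tmax <- pad(tmax)
  }
  out <- climate_stack(tmin, tmax,
                       list(xll = xll, yll = yll, cellsize = cellsize))
  attr(out, "seed") <- seed
  out
}
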