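#' @title Stochastic cohort life-table simulation
#'
#' @description The simulator advances a founding egg cohort through the
#' stages egg -> larva -> pupa -> adult (female/male) one day at a time using
#' rate summation and cohort updating:
#'
#' * each individual carries a physiological-age accumulator per stage that
#'   grows by `r(T) dt` (the Sharpe-DeMichele rate, averaged over the 96
#'   sub-daily steps under fluctuating temperatures), and a stage-completion
#'   threshold drawn once per stage from the log-logistic form of the
#'   cumulative logit development-time distribution (median 1, shape = the
#'   common logit slope); the stage is completed when the accumulator crosses
#'   the threshold;
#' * immatures additionally face a daily mortality hazard
#'   `h = 1 - (1 - m(T))^(1/D(T))`, the per-day share of the Wang stage
#'   mortality `m(T)` given the median stage duration `D(T) = 1/r(T)`, which
#'   preserves the stage-level total at constant temperature;
#' * adults age by their senescence rate and die when the senescence
#'   accumulator crosses its threshold; females lay
#'   `f(T) x [G(X_new) - G(X_old)]` eggs per day, the total fecundity
#'   apportioned by the increment of the Gamma oviposition schedule over the
#'   senescence physiological age `X`, with eggs drawn Poisson and daughters
#'   binomial with the sex ratio.
#'
#' @name lifetable
NULL

.STAGES <- c("egg", "larva", "pupa")

# log-logistic stage-completion threshold: median 1, shape = logit slope b
.sample_theta <- function(n, b) exp(stats::rlogis(n) / b)

# per-day mortality hazard from a stage-total mortality; median stage
# duration capped at 365 d so extreme temperatures still resolve
.daily_hazard <- function(m, rate, dt = 1) {
  D <- pmin(1 / pmax(rate, 1 / 365), 365)
  1 - (1 - pmin(m, 1 - 1e-12))^(dt / D)
}

#' Initialize a founding cohort population
#'
#' @param n_eggs number of founding eggs.
#' @param phenology a [phenology_model()].
#' @return an object of class `cohort_population`: parallel vectors `stage`
#'   (1 egg, 2 larva, 3 pupa, 4 adult), `phys` (current-stage physiological
#'   age), `theta` (current-stage completion threshold), `sex` (0 undecided,
#'   1 female, 2 male) and `alive`.
#' @export
init_population <- function(n_eggs, phenology) {
  stopifnot(n_eggs >= 1)
  structure(
    list(stage = rep(1L, n_eggs),
         phys = numeric(n_eggs),
         theta = .sample_theta(n_eggs, phenology$dev_time$egg$slope),
         sex = rep(0L, n_eggs),
         alive = rep(TRUE, n_eggs)),
    class = "cohort_population")
}

#' Advance a cohort population by one time step
#'
#' One step of the cohort-updating / rate-summation engine (see
#' [lifetable]).  Adults present at the step start are processed first
#' (senescence, oviposition, death), then immatures (development, mortality
#' hazard, stage transition), so a newly moulted adult starts aging on the
#' following step.
#'
#' @param population a `cohort_population` from [init_population()].
#' @param phenology a [phenology_model()].
#' @param temperature a single temperature (degrees C) or a vector of
#'   sub-daily step temperatures whose rates are averaged (rate summation).
#' @param dt_days step length in days (default 1).
#' @return a list with `population` (updated), `eggs` (eggs laid during the
#'   step) and `daughters` (female eggs among them).
#' @export
step_cohorts <- function(population, phenology, temperature, dt_days = 1) {
  stopifnot(inherits(population, "cohort_population"), dt_days > 0)
  pop <- population
  tbar <- mean(temperature)
  rate_of <- function(slot)
    mean(eval_development_rate(phenology$dev_rate[[slot]], temperature))
  r_imm <- vapply(.STAGES, rate_of, 1)
  r_sen <- c(rate_of("female"), rate_of("male"))
  fT <- eval_total_fecundity(phenology$fecundity, tbar)
  sr <- sex_ratio_at(phenology, tbar)

  eggs_laid <- 0
  daughters <- 0

  # ---- adults: senescence, oviposition, death --------------------------
  ad <- which(pop$alive & pop$stage == 4L)
  if (length(ad)) {
    r_ad <- r_sen[pop$sex[ad]]
    x_old <- pop$phys[ad]
    x_new <- x_old + r_ad * dt_days
    fem <- pop$sex[ad] == 1L
    if (any(fem)) {
      dg <- eval_oviposition_cdf(phenology$oviposition, x_new[fem]) -
        eval_oviposition_cdf(phenology$oviposition, x_old[fem])
      lam <- fT * dg
      laid <- stats::rpois(length(lam), lam)
      eggs_laid <- sum(laid)
      daughters <- if (eggs_laid > 0)
        stats::rbinom(1L, as.integer(eggs_laid), sr) else 0
    }
    pop$phys[ad] <- x_new
    dead <- x_new >= pop$theta[ad]
    pop$alive[ad[dead]] <- FALSE
  }

  # ---- immatures: development, mortality hazard, transition ------------
  # processed pupa -> egg so an individual moulting during the step is not
  # advanced again in its new stage within the same step
  for (s in rev(seq_along(.STAGES))) {
    idx <- which(pop$alive & pop$stage == s)
    if (!length(idx)) next
    pop$phys[idx] <- pop$phys[idx] + r_imm[s] * dt_days
    m <- eval_mortality(phenology$mortality[[.STAGES[s]]], tbar)
    h <- .daily_hazard(m, r_imm[s], dt_days)
    if (h > 0) {
      die <- stats::runif(length(idx)) < h
      pop$alive[idx[die]] <- FALSE
      idx <- idx[!die]
    }
    done <- idx[pop$phys[idx] >= pop$theta[idx]]
    if (length(done)) {
      if (s < 3L) {
        nxt <- .STAGES[s + 1L]
        pop$stage[done] <- s + 1L
        pop$phys[done] <- 0
        pop$theta[done] <- .sample_theta(length(done),
                                         phenology$dev_time[[nxt]]$slope)
      } else {
        # pupa -> adult: assign sex and a senescence threshold
        sx <- ifelse(stats::runif(length(done)) < sr, 1L, 2L)
        pop$stage[done] <- 4L
        pop$sex[done] <- sx
        pop$phys[done] <- 0
        slp <- ifelse(sx == 1L, phenology$dev_time$female$slope,
                      phenology$dev_time$male$slope)
        pop$theta[done] <- .sample_theta(length(done), slp)
      }
    }
  }
  list(population = pop, eggs = eggs_laid, daughters = daughters)
}

#' Demographic parameters from an lx/mx schedule
#'
#' Computes the six classical life-table parameters from survivorship `lx`
#' and daily daughters-per-female `mx` on a common age grid: gross
#' reproductive rate `GRR = sum(mx)`, net reproductive rate
#' `Ro = sum(lx mx)`, the intrinsic rate of increase `rm` solving the
#' Lotka-Euler equation `sum(exp(-rm x) lx mx) = 1` (bisection on
#' `[-1, 2]`/day, expanded to `[-5, 5]` if needed, tolerance 1e-8), the
#' finite rate `lambda = exp(rm)`, mean generation time `T = log(Ro)/rm` and
#' doubling time `Dt = log(2)/rm`.
#'
#' If `Ro <= 0` (no reproduction) the rate-based parameters are returned as
#' `NA` with flag `"no_reproduction"` rather than as an error, so
#' temperature sweeps never abort.
#'
#' @param schedule data frame with columns `age` (days), `lx`, `mx`.
#' @return a one-row data frame with columns `GRR`, `Ro`, `rm`, `lambda`,
#'   `T`, `Dt` and attribute `"flags"`.
#' @export
life_table_parameters <- function(schedule) {
  stopifnot(all(c("age", "lx", "mx") %in% names(schedule)))
  x <- schedule$age
  lxmx <- schedule$lx * schedule$mx
  Ro <- sum(lxmx)
  GRR <- sum(schedule$mx)
  flags <- character()
  if (Ro <= 0) {
    out <- data.frame(GRR = GRR, Ro = Ro, rm = NA_real_, lambda = NA_real_,
                      T = NA_real_, Dt = NA_real_)
    attr(out, "flags") <- "no_reproduction"
    return(out)
  }
  euler <- function(r) sum(exp(-r * x) * lxmx) - 1
  lo <- -1; hi <- 2
  while (euler(lo) < 0 && lo > -5) lo <- lo - 1
  while (euler(hi) > 0 && hi < 5) hi <- hi + 1
  if (euler(lo) < 0 || euler(hi) > 0) {
    rm <- NA_real_
    flags <- c(flags, "rm_bracket_failed")
  } else {
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (euler(mid) > 0) lo <- mid else hi <- mid
    }
    rm <- (lo + hi) / 2
  }
  out <- data.frame(
    GRR = GRR, Ro = Ro, rm = rm, lambda = exp(rm),
    T = if (!is.na(rm) && rm != 0) log(Ro) / rm else NA_real_,
    Dt = if (!is.na(rm) && rm != 0) log(2) / rm else NA_real_)
  attr(out, "flags") <- flags
  out
}

.day_temps <- function(temperatures, day) {
  if (inherits(temperatures, "temperature_series")) {
    n <- nrow(temperatures)
    daily_profile(((day - 1L) %% n) + 1L, temperatures)
  } else {
    temperatures
  }
}

#' Simulate life tables for a founding egg cohort
#'
#' Runs `reps` independent stochastic replicates of the cohort-updating /
#' rate-summation engine (see [lifetable]) at a constant temperature or over
#' a daily min/max [temperature_series()] (expanded to 96 sub-daily steps by
#' the cosine interpolator; the series is recycled if a replicate outlives
#' it).  Each replicate records the survivorship of the founding cohort
#' (`lx`, both sexes) and the daughters laid per alive member per day (`mx`),
#' and computes the six demographic parameters; the result carries the
#' per-replicate values and their across-replicate mean and SD.
#'
#' Replicates at temperatures where nobody reproduces return `Ro = 0` with
#' the flag `"no_reproduction"` (never an error).
#'
#' @param phenology a [phenology_model()].
#' @param temperatures a single constant temperature (degrees C) or a
#'   [temperature_series()].
#' @param n_eggs founding cohort size (default 100).
#' @param reps number of replicates (default 10).
#' @param seed integer seed; one seed drives per-replicate independent
#'   streams and is recorded in the result.
#' @param max_days hard cap on simulated days per replicate (default 2000;
#'   hitting it sets flag `"truncated"`).
#' @param keep_schedules keep each replicate's lx/mx schedule.
#' @return an object of class `life_table_result`: list with `per_rep` (data
#'   frame of the six parameters per replicate), `summary` (mean and sd per
#'   parameter), `flags`, `n_reps`, `seed`, `temperature`, and optionally
#'   `schedules`.
#' @export
simulate_life_table <- function(phenology, temperatures, n_eggs = 100,
                                reps = 10, seed = NULL, max_days = 2000,
                                keep_schedules = FALSE) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  per <- vector("list", reps)
  schedules <- if (keep_schedules) vector("list", reps) else NULL
  flags <- character()
  for (k in seq_len(reps)) {
    set.seed(rep_seeds[k])
    pop <- init_population(n_eggs, phenology)
    alive <- integer(0); daughters <- numeric(0)
    day <- 0L
    while (any(pop$alive) && day < max_days) {
      day <- day + 1L
      alive[day] <- sum(pop$alive)
      st <- step_cohorts(pop, phenology, .day_temps(temperatures, day))
      pop <- st$population
      daughters[day] <- st$daughters
    }
    if (day >= max_days && any(pop$alive)) flags <- union(flags, "truncated")
    sched <- data.frame(age = seq_len(day), lx = alive / n_eggs,
                        mx = ifelse(alive > 0, daughters / alive, 0))
    p <- life_table_parameters(sched)
    flags <- union(flags, attr(p, "flags"))
    per[[k]] <- cbind(rep = k, p)
    if (keep_schedules) schedules[[k]] <- sched
  }
  per <- do.call(rbind, per)
  vars <- c("GRR", "Ro", "rm", "lambda", "T", "Dt")
  summ <- data.frame(
    parameter = vars,
    mean = vapply(vars, function(v) mean(per[[v]], na.rm = TRUE), 1),
    sd = vapply(vars, function(v) stats::sd(per[[v]], na.rm = TRUE), 1),
    row.names = NULL)
  structure(
    list(per_rep = per, summary = summ, flags = flags, n_reps = reps,
         seed = seed, temperature = temperatures, schedules = schedules),
    class = "life_table_result")
}

#' @export
print.life_table_result <- function(x, ...) {
  tt <- x$temperature
  cat("Life-table simulation (", x$n_reps, " replicates",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  if (is.numeric(tt) && length(tt) == 1L)
    cat("  constant temperature:", tt, "C\n")
  else cat("  fluctuating temperatures (daily series)\n")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 3)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic expected life table at a constant temperature
#'
#' An independent, randomness-free oracle for the stochastic simulator.
#' Expected stage-entry distributions are propagated by direct convolution:
#' the day-resolution stage-duration law comes from the logit distribution
#' discretized through the rate accumulator
#' (`P(dur = d) = F(d r) - F((d-1) r)` with `F` the log-logistic threshold
#' law), within-stage survival applies the daily hazard, adult survival uses
#' the sex-specific senescence law, and expected daughters per day apportion
#' `f(T)` by Gamma-schedule increments.  The returned schedule has the same
#' `lx`/`mx` definitions as the stochastic engine, so at large cohort sizes
#' the two agree in expectation.
#'
#' @param phenology a [phenology_model()].
#' @param temperature a single constant temperature, degrees C.
#' @param horizon maximum age in days (default adaptive, capped at 5000).
#' @return a schedule data frame (`age`, `lx`, `mx`) with attribute
#'   `"parameters"` holding [life_table_parameters()] of the schedule.
#' @export
deterministic_life_table <- function(phenology, temperature, horizon = NULL) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  rate_of <- function(slot)
    eval_development_rate(phenology$dev_rate[[slot]], temperature)
  r_imm <- vapply(.STAGES, rate_of, 1)
  r_sen <- c(female = rate_of("female"), male = rate_of("male"))
  if (is.null(horizon)) {
    horizon <- ceiling(6 * sum(1 / pmax(c(r_imm, r_sen["female"]), 1 / 365)))
    horizon <- min(max(horizon, 200L), 5000L)
  }
  H <- horizon
  sr <- sex_ratio_at(phenology, temperature)
  fT <- eval_total_fecundity(phenology$fecundity, temperature)

  Fcdf <- function(u, b) ifelse(u <= 0, 0, stats::plogis(b * log(u)))
  conv_at <- function(a, w) {
    # c[x] = sum_k a[x-k] w[k+1], k = 0..len(w)-1, truncated to H
    out <- numeric(H)
    nz <- which(a > 0)
    for (u in nz) {
      kmax <- min(length(w), H - u + 1L)
      if (kmax >= 1L)
        out[u:(u + kmax - 1L)] <- out[u:(u + kmax - 1L)] + a[u] * w[seq_len(kmax)]
    }
    out
  }

  enter <- numeric(H); enter[1] <- 1   # founding eggs: first day of life
  alive_imm <- numeric(H)
  for (s in seq_along(.STAGES)) {
    b <- phenology$dev_time[[.STAGES[s]]]$slope
    r <- r_imm[s]
    m <- eval_mortality(phenology$mortality[[.STAGES[s]]], temperature)
    h <- .daily_hazard(m, r)
    d <- seq_len(H)
    Pdur <- Fcdf(d * r, b) - Fcdf((d - 1) * r, b)
    # alive in this stage k full days after entry: survived k hazard days and
    # duration exceeds k
    k <- 0:(H - 1)
    surv_in <- (1 - h)^k * (1 - Fcdf(k * r, b))
    alive_imm <- alive_imm + conv_at(enter, surv_in)
    # entry into the next stage: complete after d days, having survived them
    w_next <- Pdur * (1 - h)^d
    nxt <- numeric(H)
    nz <- which(enter > 0)
    for (u in nz) {
      dmax <- min(H, H - u)
      if (dmax >= 1L) {
        ii <- u + seq_len(dmax)
        nxt[ii] <- nxt[ii] + enter[u] * w_next[seq_len(dmax)]
      }
    }
    enter <- nxt
  }
  A <- enter  # adult-entry distribution (first adult day)

  k <- 0:(H - 1)
  S_F <- 1 - Fcdf(k * r_sen["female"], phenology$dev_time$female$slope)
  S_M <- 1 - Fcdf(k * r_sen["male"], phenology$dev_time$male$slope)
  alive_ad <- sr * conv_at(A, S_F) + (1 - sr) * conv_at(A, S_M)

  rF <- r_sen[["female"]]
  G <- function(u) eval_oviposition_cdf(phenology$oviposition, pmax(u, 0))
  dG <- G((k + 1) * rF) - G(k * rF)   # laying during adult day k+1
  daughters <- sr^2 * fT * conv_at(A, S_F * dG)

  alive <- pmin(alive_imm + alive_ad, 1)
  keep <- max(which(alive > 1e-12), 1L)
  sched <- data.frame(age = seq_len(keep), lx = alive[seq_len(keep)],
                      mx = ifelse(alive[seq_len(keep)] > 0,
                                  daughters[seq_len(keep)] / alive[seq_len(keep)],
                                  0))
  attr(sched, "parameters") <- life_table_parameters(sched)
  sched
}

#' Quadratic response of a life-table parameter to temperature
#'
#' Least-squares fit of `L(T) = a + b T + c T^2` to a parameter estimated at
#' several temperatures.  The fitted temperature range is stored and
#' evaluation outside it is clipped with a warning, since the quadratic has
#' no meaning beyond the data.
#'
#' @param results either a data frame with columns `temperature` and `value`,
#'   or a named list of [simulate_life_table()] results keyed by temperature,
#'   combined with `parameter`.
#' @param parameter name of the life-table parameter (`"rm"`, `"T"`, ...)
#'   when `results` is a list of simulation results.
#' @return an object of class `parameter_response` with fields `a`, `b`, `c`,
#'   `parameter`, `range`.
#' @export
fit_parameter_response <- function(results, parameter = NULL) {
  if (is.data.frame(results)) {
    tab <- data.frame(temperature = results$temperature,
                      value = results$value)
  } else {
    stopifnot(!is.null(parameter))
    tab <- do.call(rbind, lapply(names(results), function(tc) {
      s <- results[[tc]]$summary
      data.frame(temperature = as.numeric(tc),
                 value = s$mean[s$parameter == parameter])
    }))
  }
  tab <- tab[is.finite(tab$value), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need >= 3 temperatures with defined values")
  fit <- stats::lm(value ~ temperature + I(temperature^2), data = tab)
  cf <- unname(stats::coef(fit))
  structure(list(parameter = parameter %||% "value", a = cf[1], b = cf[2],
                 c = cf[3], range = range(tab$temperature)),
            class = "parameter_response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted parameter response
#'
#' @param response a `parameter_response` from [fit_parameter_response()].
#' @param temperature degrees C (vectorized).
#' @param clip clip temperatures to the fitted range (default `TRUE`, with a
#'   warning when clipping occurs); `FALSE` raises an error outside the
#'   range.
#' @return predicted parameter values.
#' @export
eval_parameter_response <- function(response, temperature, clip = TRUE) {
  stopifnot(inherits(response, "parameter_response"))
  rng <- response$range
  out_of <- temperature < rng[1] | temperature > rng[2]
  if (any(out_of)) {
    if (!clip) stop("temperature outside fitted range [",
                    rng[1], ", ", rng[2], "]")
    warning("extrapolation clipped to fitted range [",
            rng[1], ", ", rng[2], "] for ", sum(out_of), " value(s)")
    temperature <- pmin(pmax(temperature, rng[1]), rng[2])
  }
  response$a + response$b * temperature + response$c * temperature^2
}

#' Compare predicted life-table values with observations
#'
#' @param predicted data frame with columns `parameter` and `value` (e.g.
#'   simulated under a fluctuating-temperature regime).
#' @param observed data frame with columns `parameter` and `value` from an
#'   independent experiment.
#' @return a data frame with predicted, observed, absolute and relative
#'   differences per parameter.  No hypothesis testing is performed.
#' @export
validate_against_observations <- function(predicted, observed) {
  if (!nrow(observed)) stop("empty observed table")
  miss <- setdiff(predicted$parameter, observed$parameter)
  if (length(miss))
    stop("observed table lacks parameters: ", paste(miss, collapse = ", "))
  m <- match(predicted$parameter, observed$parameter)
  data.frame(
    parameter = predicted$parameter,
    predicted = predicted$value,
    observed = observed$value[m],
    difference = predicted$value - observed$value[m],
    relative = (predicted$value - observed$value[m]) / observed$value[m])
}
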