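#' Assemble a complete phenology model
#'
#' Bundles the fitted thermal sub-models for every life stage into the single
#' parameter artifact consumed by the life-table simulator and the risk
#' indices: per-stage development/senescence time distributions and
#' Sharpe-DeMichele rate curves, per-immature-stage Wang mortality curves,
#' the total fecundity curve, the Gamma oviposition schedule, and the
#' proportion of female progeny per temperature.
#'
#' @param dev_time named list of [dev_time_dist()] objects for `egg`,
#'   `larva`, `pupa`, `female`, `male`.
#' @param dev_rate named list of [dev_rate_model()] objects for the same five
#'   slots (adult slots describe senescence).
#' @param mortality named list of [mortality_model()] objects for `egg`,
#'   `larva`, `pupa`.
#' @param fecundity a [fecundity_model()].
#' @param oviposition an [oviposition_model()].
#' @param sex_ratio proportion of female progeny: either a single number or a
#'   named numeric vector by temperature (degrees C), values in `[0, 1]`.
#'   Temperature-specific values are linearly interpolated (constant beyond
#'   the ends).
#' @return an object of class `phenology_model`.
#' @export
phenology_model <- function(dev_time, dev_rate, mortality, fecundity,
                            oviposition, sex_ratio = 0.5) {
  need <- c("egg", "larva", "pupa", "female", "male")
  if (!all(need %in% names(dev_time)))
    stop("dev_time must have slots: ", paste(need, collapse = ", "))
  if (!all(need %in% names(dev_rate)))
    stop("dev_rate must have slots: ", paste(need, collapse = ", "))
  if (!all(c("egg", "larva", "pupa") %in% names(mortality)))
    stop("mortality must have slots egg, larva, pupa")
  if (any(sex_ratio < 0 | sex_ratio > 1)) stop("sex_ratio must lie in [0, 1]")
  structure(
    list(dev_time = dev_time, dev_rate = dev_rate, mortality = mortality,
         fecundity = fecundity, oviposition = oviposition,
         sex_ratio = sex_ratio),
    class = "phenology_model")
}

#' @export
print.phenology_model <- function(x, ...) {
  cat("Phenology model: 3 immature stages + 2 adult sexes\n")
  cat("  fecundity form:", x$fecundity$form, "\n")
  cat("  oviposition gamma: shape", format(x$oviposition$shape),
      "rate", format(x$oviposition$rate), "\n")
  sr <- x$sex_ratio
  cat("  sex ratio:", if (length(sr) == 1L) format(sr) else
    paste0(names(sr), "C=", sr, collapse = " "), "\n")
  invisible(x)
}

#' Proportion of female progeny at a temperature
#' @param phenology a [phenology_model()].
#' @param temperature degrees C.
#' @return proportion female in `[0, 1]`.
#' @export
sex_ratio_at <- function(phenology, temperature) {
  sr <- phenology$sex_ratio
  if (length(sr) == 1L) return(rep(unname(sr), length(temperature)))
  tt <- as.numeric(names(sr))
  stats::approx(tt, sr, xout = temperature, rule = 2)$y
}

.PHENOLOGY_FORMAT_VERSION <- "1.0"

#' Write a phenology model to a JSON parameter file
#'
#' The file is self-contained: one named block per stage and sub-model, a
#' format version, and the gas constant pinned to 1.987 cal/(K mol).
#'
#' @param phenology a [phenology_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenology <- function(phenology, path) {
  stopifnot(inherits(phenology, "phenology_model"))
  strip <- function(m) {
    m <- unclass(m)
    m$flags <- as.list(m$flags)
    m
  }
  obj <- list(
    format_version = .PHENOLOGY_FORMAT_VERSION,
    gas_constant = R_GAS,
    dev_time = lapply(phenology$dev_time, function(d) list(
      stage = d$stage, intercepts = as.list(d$intercepts), slope = d$slope,
      aic = d$aic, r2 = d$r2, flags = as.list(d$flags))),
    dev_rate = lapply(phenology$dev_rate, strip),
    mortality = lapply(phenology$mortality, strip),
    fecundity = unclass(phenology$fecundity),
    oviposition = unclass(phenology$oviposition),
    sex_ratio = if (length(phenology$sex_ratio) == 1L)
      unname(phenology$sex_ratio) else as.list(phenology$sex_ratio))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a phenology model from a JSON parameter file
#'
#' @param path file written by [write_phenology()].
#' @return a [phenology_model()].
#' @export
read_phenology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  dt <- lapply(obj$dev_time, function(d)
    dev_time_dist(d$stage, unlist(d$intercepts), d$slope, num(d$aic),
                  num(d$r2), as.character(unlist(d$flags))))
  dr <- lapply(obj$dev_rate, function(d)
    dev_rate_model(d$stage, d$p, d$To, d$dHa, d$dHh, d$Th, num(d$aic),
                   num(d$r2), as.character(unlist(d$flags))))
  mo <- lapply(obj$mortality, function(d)
    mortality_model(d$stage, d$Topt, d$B, d$H, num(d$aic), num(d$r2),
                    as.character(unlist(d$flags))))
  fe <- fecundity_model(obj$fecundity$form, obj$fecundity$a, obj$fecundity$b,
                        obj$fecundity$c, num(obj$fecundity$aic),
                        num(obj$fecundity$r2))
  ov <- oviposition_model(obj$oviposition$shape, obj$oviposition$rate,
                          num(obj$oviposition$aic), num(obj$oviposition$r2))
  sr <- obj$sex_ratio
  sr <- if (is.list(sr)) unlist(sr) else sr
  phenology_model(dt, dr, mo, fe, ov, sr)
}

# Reference constant-temperature life-table summaries for Spodoptera litura
# reared on soybean: logit development-time parameters, Sharpe-DeMichele
# development-rate parameters for the immatures, Wang mortality parameters,
# the exponential-quadratic fecundity curve and the Gamma oviposition
# schedule, plus mean adult senescence times used to refit the (unpublished)
# adult senescence rate curves.
.slitura <- list(
  temps = c(15, 20, 25, 30, 35, 38),
  logit = list(
    egg    = list(a = c(-26.71, -15.94, -13.46, -6.93, -5.91, -9.38),  b = 10.51),
    larva  = list(a = c(-148.20, -107.52, -93.81, -89.49, -77.69, -85.21), b = 32.76),
    pupa   = list(a = c(-58.53, -47.33, -41.45, -37.56, -31.06, -38.06),  b = 17.23),
    female = list(a = c(-44.65, -33.837, -27.12, -25.87, -23.42, -22.15), b = 13.36),
    male   = list(a = c(-29.77, -22.82, -19.35, -15.58, -14.52, -13.29),  b = 9.22)),
  sharpe = list(
    egg   = list(p = 0.29, To = 297.65, dHa = 19159.01, dHh = 78167.42,  Th = 309.34),
    larva = list(p = 0.05, To = 299.67, dHa = 13147.58, dHh = 122073.27, Th = 311.67),
    pupa  = list(p = 0.10, To = 299.49, dHa = 11600.88, dHh = 1043640.95, Th = 311.19)),
  wang = list(
    egg   = list(Topt = 26.18, B = 2.38, H = 0.01),
    larva = list(Topt = 26.33, B = 3.92, H = 0.10),
    pupa  = list(Topt = 28.53, B = 1.63, H = 0.01)),
  fecundity = c(a = -13.30, b = 1.59, c = -0.03),
  oviposition = c(shape = 5.99, rate = 10.32),
  senescence_days = list(
    female = c(28.30, 12.60, 7.62, 6.94, 5.78, 5.25),
    male   = c(25.29, 11.89, 8.16, 5.42, 4.83, 4.23)),
  observed_days = list(   # observed mean development / senescence times
    egg    = c(14.0, 5.0, 4.0, 2.0, 2.0, 3.0),
    larva  = c(93.0, 27.0, 18.0, 16.0, 11.0, 14.0),
    pupa   = c(31.0, 16.0, 12.0, 9.0, 7.0, 10.0),
    female = c(29.0, 13.0, 8.0, 7.5, 6.0, 6.0),
    male   = c(27.0, 12.0, 8.5, 6.0, 6.0, 5.0)))

#' Reference phenology model for *Spodoptera litura* on soybean
#'
#' Builds a complete [phenology_model()] from a reference constant-temperature
#' life-table study of the common cutworm *Spodoptera litura* reared on
#' soybean at 15-38 degrees C: cumulative logit development-time parameters
#' for all five stage slots, Sharpe-DeMichele development-rate parameters for
#' the immature stages, Wang mortality parameters, the exponential-quadratic
#' fecundity curve `exp(-13.30 + 1.59 T - 0.03 T^2)`, and the Gamma
#' oviposition schedule (shape 5.99, rate 10.32).
#'
#' Adult senescence rate curves were not part of the reference parameter set;
#' they are refit here, at construction time, from the reference mean
#' senescence times (rate = 1/mean days).  Senescence rates increase
#' monotonically over the tested range, so the high-temperature inactivation
#' branch is unidentifiable and `Th` pins at its upper bound (flagged); the
#' fitted curves are used only inside the tested range.  The sex ratio
#' defaults to 0.5 at all temperatures, the study design value.
#'
#' @param sex_ratio proportion of female progeny (default 0.5).
#' @return a [phenology_model()].
#' @export
slitura_phenology <- function(sex_ratio = 0.5) {
  tt <- .slitura$temps
  dt <- lapply(names(.slitura$logit), function(s) {
    p <- .slitura$logit[[s]]
    dev_time_dist(s, stats::setNames(p$a, tt), p$b)
  })
  names(dt) <- names(.slitura$logit)
  dr <- lapply(names(.slitura$sharpe), function(s) {
    p <- .slitura$sharpe[[s]]
    dev_rate_model(s, p$p, p$To, p$dHa, p$dHh, p$Th)
  })
  names(dr) <- names(.slitura$sharpe)
  for (s in c("female", "male")) {
    r <- 1 / .slitura$senescence_days[[s]]
    dr[[s]] <- fit_development_rate(stats::setNames(r, tt), stage = s)
  }
  mo <- lapply(names(.slitura$wang), function(s) {
    p <- .slitura$wang[[s]]
    mortality_model(s, p$Topt, p$B, p$H)
  })
  names(mo) <- names(.slitura$wang)
  fe <- fecundity_model("exp_quadratic", .slitura$fecundity[["a"]],
                        .slitura$fecundity[["b"]], .slitura$fecundity[["c"]])
  ov <- oviposition_model(.slitura$oviposition[["shape"]],
                          .slitura$oviposition[["rate"]])
  phenology_model(dt, dr, mo, fe, ov, sex_ratio)
}

#' Reference observed life-table summaries for *Spodoptera litura*
#'
#' Observed mean development (immatures) and senescence (adults) times in
#' days by constant rearing temperature, from the same reference study as
#' [slitura_phenology()].  Useful for refitting rate curves from summary
#' data and for validation examples.
#'
#' @return a data frame with columns `stage`, `temperature_C`, `mean_days`.
#' @export
slitura_observed_times <- function() {
  tt <- .slitura$temps
  do.call(rbind, lapply(names(.slitura$observed_days), function(s)
    data.frame(stage = s, temperature_C = tt,
               mean_days = .slitura$observed_days[[s]])))
}

#' Read cohort observations from CSV
#'
#' Expected columns: `stage`, `temperature_C`, `individual_id`, `outcome`
#' (`completed`, `died` or `censored`), `event_day`, and optionally
#' `eggs_day_1` ... `eggs_day_n` on female rows (daily egg counts from adult
#' day 1 onward).
#'
#' @param path CSV file path (UTF-8, header required).
#' @return an object of class `cohort_data`: a list with `records` (the event
#'   table) and `eggs` (long-format daily egg counts with columns
#'   `temperature_C`, `female_id`, `age_day`, `eggs`, possibly empty).
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "temperature_C", "individual_id", "outcome", "event_day")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  eggcols <- grep("^eggs_day_", names(df), value = TRUE)
  eggs <- data.frame(temperature_C = numeric(), female_id = character(),
                     age_day = integer(), eggs = numeric())
  if (length(eggcols)) {
    fem <- df[df$stage == "female", , drop = FALSE]
    if (nrow(fem)) {
      days <- as.integer(sub("^eggs_day_", "", eggcols))
      long <- do.call(rbind, lapply(seq_along(eggcols), function(j) {
        v <- fem[[eggcols[j]]]
        keep <- !is.na(v)
        if (!any(keep)) return(NULL)
        data.frame(temperature_C = fem$temperature_C[keep],
                   female_id = as.character(fem$individual_id[keep]),
                   age_day = days[j], eggs = v[keep])
      }))
      if (!is.null(long)) eggs <- long[order(long$female_id, long$age_day), ]
    }
  }
  cohort_data(df[, need], eggs)
}

#' Construct a cohort data object
#'
#' @param records event table (see [read_cohort_csv()] for columns).
#' @param eggs long-format daily egg counts (may be empty).
#' @return an object of class `cohort_data`.
#' @export
cohort_data <- function(records, eggs = NULL) {
  if (is.null(eggs))
    eggs <- data.frame(temperature_C = numeric(), female_id = character(),
                       age_day = integer(), eggs = numeric())
  if (any(records$event_day < 1)) stop("event_day must be >= 1")
  if (nrow(eggs) && any(eggs$eggs < 0)) stop("egg counts must be >= 0")
  structure(list(records = records, eggs = eggs), class = "cohort_data")
}

#' Write cohort observations to CSV
#'
#' Inverse of [read_cohort_csv()]: daily egg counts are spread into
#' `eggs_day_*` columns on female rows.
#'
#' @param cohort a `cohort_data` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  df <- cohort$records
  eggs <- cohort$eggs
  if (nrow(eggs)) {
    dmax <- max(eggs$age_day)
    for (j in seq_len(dmax)) df[[paste0("eggs_day_", j)]] <- NA_real_
    key <- paste(df$temperature_C, df$individual_id)
    for (i in seq_len(nrow(eggs))) {
      row <- which(df$stage == "female" &
                   key == paste(eggs$temperature_C[i], eggs$female_id[i]))
      if (length(row))
        df[row[1], paste0("eggs_day_", eggs$age_day[i])] <- eggs$eggs[i]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit a complete phenology model from cohort observations
#'
#' Runs every sub-model fit against a multi-temperature cohort data set:
#' logit development-time distributions per stage, Sharpe-DeMichele rate
#' curves from the per-temperature mean times (rate = 1/mean), Wang mortality
#' curves from the per-temperature death fractions of the immature stages,
#' the exponential-quadratic fecundity curve from mean total eggs per female,
#' the Gamma oviposition schedule from pooled normalized egg-laying ages, and
#' the per-temperature sex ratio from the adult records.
#'
#' @param cohort a `cohort_data` object covering all five stage slots.
#' @return a list with elements `phenology` (the fitted [phenology_model()])
#'   and `goodness` (a data frame of AIC/R2 per sub-model).
#' @export
fit_phenology <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  rec <- cohort$records
  stages <- c("egg", "larva", "pupa", "female", "male")
  dt <- list(); dr <- list(); mo <- list()
  for (s in stages) {
    sub <- rec[rec$stage == s, , drop = FALSE]
    if (!nrow(sub)) stop("no records for stage ", s)
    dt[[s]] <- fit_dev_time_distribution(sub, stage = s)
    comp <- sub[sub$outcome == "completed", ]
    mean_days <- tapply(comp$event_day, comp$temperature_C, mean)
    if (length(mean_days) < 5L)
      stop("stage ", s, " has completers at only ", length(mean_days),
           " temperatures; at least 5 are needed for the rate curve")
    dr[[s]] <- fit_development_rate(1 / mean_days, stage = s)
    if (s %in% c("egg", "larva", "pupa")) {
      died <- tapply(sub$outcome == "died", sub$temperature_C, mean)
      mo[[s]] <- fit_mortality(died, stage = s)
    }
  }
  # fecundity: mean lifetime eggs per female per temperature
  eggs <- cohort$eggs
  if (!nrow(eggs)) stop("no daily egg counts on female records")
  tot <- stats::aggregate(eggs ~ temperature_C + female_id, eggs, sum)
  fec <- tapply(tot$eggs, tot$temperature_C, mean)
  fe <- fit_total_fecundity(fec)
  # oviposition: pooled cumulative fractions on normalized age, per
  # temperature with nonzero laying, normalized by mean female lifespan there
  fem <- rec[rec$stage == "female" & rec$outcome == "completed", ]
  life <- tapply(fem$event_day, fem$temperature_C, mean)
  pool <- do.call(rbind, lapply(names(life), function(tc) {
    e <- eggs[eggs$temperature_C == as.numeric(tc), ]
    if (!nrow(e) || sum(e$eggs) == 0) return(NULL)
    daily <- tapply(e$eggs, e$age_day, sum)
    data.frame(X = as.numeric(names(daily)) / life[[tc]],
               cumfrac = cumsum(daily) / sum(daily))
  }))
  ov <- fit_oviposition(pool$X, pool$cumfrac)
  # sex ratio per temperature from adult records
  ad <- rec[rec$stage %in% c("female", "male"), ]
  srt <- tapply(ad$stage == "female", ad$temperature_C, mean)
  sr <- stats::setNames(as.numeric(srt), names(srt))
  ph <- phenology_model(dt, dr, mo, fe, ov, sr)
  gather <- function(lst, kind)
    do.call(rbind, lapply(names(lst), function(s)
      data.frame(submodel = kind, stage = s, aic = lst[[s]]$aic,
                 r2 = lst[[s]]$r2)))
  goodness <- rbind(
    gather(dt, "dev_time"), gather(dr, "dev_rate"), gather(mo, "mortality"),
    data.frame(submodel = "fecundity", stage = "female", aic = fe$aic,
               r2 = fe$r2),
    data.frame(submodel = "oviposition", stage = "female", aic = ov$aic,
               r2 = ov$r2))
  list(phenology = ph, goodness = goodness)
}
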