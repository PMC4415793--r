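#' Pipeline run configuration
#'
#' A flat configuration for [run_pipeline()], serialized verbatim (YAML)
#' into every run directory.  Paths that are `NULL` or missing cause the
#' corresponding stage to be skipped.
#'
#' @param cohort_csv cohort observations CSV (fit stage input).
#' @param phenology_json previously fitted parameter file; used instead of
#'   fitting when `cohort_csv` is absent.  When both are absent the
#'   *S. litura* reference parameterization is used.
#' @param weather_csv daily weather CSV for a fluctuating-temperature
#'   simulation.
#' @param climate_dir directory of 24 monthly `tmin_*/tmax_*` ASCII grids
#'   (map stage input).
#' @param future_climate_dir second climatology for change maps.
#' @param mask_asc optional 0/1 ASCII grid mask.
#' @param out_dir run output directory.
#' @param constant_temps constant simulation temperatures, degrees C.
#' @param n_eggs,reps founding cohort size and replicate count per
#'   temperature.
#' @param seed integer seed for all stochastic stages.
#' @param mortality_cutoff survivability cutoff for the risk indices.
#' @return a list of class `run_config`.
#' @export
run_config <- function(cohort_csv = NULL, phenology_json = NULL,
                       weather_csv = NULL, climate_dir = NULL,
                       future_climate_dir = NULL, mask_asc = NULL,
                       out_dir = "phenorisk_run",
                       constant_temps = c(15, 20, 25, 30, 35, 38),
                       n_eggs = 100, reps = 10, seed = 1,
                       mortality_cutoff = 0.99) {
  cfg <- list(cohort_csv = cohort_csv, phenology_json = phenology_json,
              weather_csv = weather_csv, climate_dir = climate_dir,
              future_climate_dir = future_climate_dir, mask_asc = mask_asc,
              out_dir = out_dir, constant_temps = constant_temps,
              n_eggs = n_eggs, reps = reps, seed = seed,
              mortality_cutoff = mortality_cutoff)
  for (p in c("cohort_csv", "phenology_json", "weather_csv", "climate_dir",
              "future_climate_dir", "mask_asc"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured path does not exist: ", p, " = ", cfg[[p]])
  structure(cfg, class = c("run_config", "list"))
}

# deterministic polynomial hash of a string, 8 hex digits; stamps artifacts
.config_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the fit / simulate / map pipeline
#'
#' Executes the three stages in order, skipping any stage whose inputs are
#' not configured, and writes all artifacts into the run directory together
#' with the verbatim configuration, a plain-text log and a machine-readable
#' manifest (config hash, seed, stage status, output paths).
#'
#' * **fit** — fit all sub-models from the cohort CSV (or load a parameter
#'   file, or fall back to the reference parameterization); writes
#'   `phenology.json` and `goodness.csv`.
#' * **simulate** — stochastic life tables at each configured constant
#'   temperature (and over the weather series if given); writes
#'   per-replicate and summary CSVs and fits the quadratic temperature
#'   responses of mean generation time and intrinsic rate needed by the map
#'   stage.
#' * **map** — risk indices over the climatology grids; writes
#'   `ERI.asc`/`GI.asc`/`AI.asc`, masked if a mask is given, plus change
#'   layers against a second climatology when configured.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted `phenology`, the simulation
#'   `results`, fitted `responses`, any `grids`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(unclass(config))
  writeLines(cfg_yaml, file.path(out, "config.yaml"))
  hash <- .config_hash(cfg_yaml)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("run start; config hash ", hash, "; seed ", config$seed)
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  outputs <- character()

  # ---- fit -------------------------------------------------------------
  goodness <- NULL
  if (!is.null(config$cohort_csv)) {
    logline("fit: fitting sub-models from ", config$cohort_csv)
    fitres <- fit_phenology(read_cohort_csv(config$cohort_csv))
    phenology <- fitres$phenology
    goodness <- fitres$goodness
    manifest$stages$fit <- "fitted"
  } else if (!is.null(config$phenology_json)) {
    logline("fit: loading parameter file ", config$phenology_json)
    phenology <- read_phenology(config$phenology_json)
    manifest$stages$fit <- "loaded"
  } else {
    logline("fit: no cohort data; using the S. litura reference parameters")
    phenology <- slitura_phenology()
    manifest$stages$fit <- "reference"
  }
  pj <- file.path(out, "phenology.json")
  write_phenology(phenology, pj)
  outputs <- c(outputs, pj)
  if (!is.null(goodness)) {
    gp <- file.path(out, "goodness.csv")
    utils::write.csv(goodness, gp, row.names = FALSE)
    outputs <- c(outputs, gp)
  }

  # ---- simulate --------------------------------------------------------
  results <- NULL; responses <- NULL
  if (length(config$constant_temps)) {
    logline("simulate: constant temperatures ",
            paste(config$constant_temps, collapse = ", "))
    results <- list()
    for (tc in config$constant_temps)
      results[[as.character(tc)]] <- simulate_life_table(
        phenology, tc, n_eggs = config$n_eggs, reps = config$reps,
        seed = config$seed + round(tc * 100))
    summ <- do.call(rbind, lapply(names(results), function(tc)
      cbind(temperature_C = as.numeric(tc), results[[tc]]$summary)))
    sp <- file.path(out, "life_table_summary.csv")
    utils::write.csv(summ, sp, row.names = FALSE)
    rp <- file.path(out, "life_table_replicates.csv")
    utils::write.csv(do.call(rbind, lapply(names(results), function(tc)
      cbind(temperature_C = as.numeric(tc), results[[tc]]$per_rep))),
      rp, row.names = FALSE)
    outputs <- c(outputs, sp, rp)
    defined <- vapply(results, function(r)
      is.finite(r$summary$mean[r$summary$parameter == "rm"]), TRUE)
    if (sum(defined) >= 3) {
      responses <- list(
        rm = fit_parameter_response(results[defined], "rm"),
        T = fit_parameter_response(results[defined], "T"))
      logline("simulate: fitted quadratic responses for rm and T over ",
              sum(defined), " temperatures")
    } else {
      logline("simulate: fewer than 3 temperatures with defined rm; ",
              "no responses fitted")
    }
    manifest$stages$simulate <- "done"
  } else manifest$stages$simulate <- "skipped"
  if (!is.null(config$weather_csv)) {
    logline("simulate: fluctuating-temperature run from ",
            config$weather_csv)
    flres <- simulate_life_table(phenology,
                                 read_weather_csv(config$weather_csv),
                                 n_eggs = config$n_eggs,
                                 reps = config$reps, seed = config$seed)
    fp <- file.path(out, "life_table_fluctuating.csv")
    utils::write.csv(cbind(regime = "fluctuating", flres$summary), fp,
                     row.names = FALSE)
    outputs <- c(outputs, fp)
    if (is.null(results)) results <- list()
    results[["fluctuating"]] <- flres
  }

  # ---- map -------------------------------------------------------------
  grids <- NULL
  if (!is.null(config$climate_dir) && !is.null(responses)) {
    logline("map: computing risk indices over ", config$climate_dir)
    cfgr <- risk_config(mortality_cutoff = config$mortality_cutoff)
    baseline <- grid_risk(read_climate_stack(config$climate_dir),
                          phenology, responses, cfgr)
    if (!is.null(config$mask_asc)) {
      mk <- read_ascii_grid(config$mask_asc)
      baseline <- apply_mask(baseline, mk$data)
      logline("map: mask applied from ", config$mask_asc)
    }
    outputs <- c(outputs, write_risk_grid(baseline, out))
    grids <- list(baseline = baseline)
    if (!is.null(config$future_climate_dir)) {
      future <- grid_risk(read_climate_stack(config$future_climate_dir),
                          phenology, responses, cfgr)
      if (!is.null(config$mask_asc))
        future <- apply_mask(future, read_ascii_grid(config$mask_asc)$data)
      outputs <- c(outputs, write_risk_grid(future, out, prefix = "future_"))
      chg <- change_map(baseline, future)
      outputs <- c(outputs, write_risk_grid(chg, out))
      grids$future <- future
      grids$change <- chg
      logline("map: change layers written")
    }
    manifest$stages$map <- "done"
  } else {
    manifest$stages$map <-
      if (is.null(config$climate_dir)) "skipped" else "skipped_no_responses"
    if (!is.null(config$climate_dir) && is.null(responses))
      logline("map: skipped, no parameter responses available")
  }

  manifest$outputs <- as.character(outputs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("run complete: ", length(outputs), " artifacts")
  invisible(list(phenology = phenology, results = results,
                 responses = responses, grids = grids,
                 manifest = manifest))
}
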