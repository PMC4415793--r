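#' Establishment risk index
#'
#' `ERI = (1 - x_egg)(1 - x_larva)(1 - x_pupa)` where each `x` is the
#' fraction of days in the year on which that immature stage could not
#' survive.  `ERI = 1` means every stage can survive year-round; a single
#' stage lethal all year forces `ERI = 0`.
#'
#' @param x_egg,x_larva,x_pupa non-survivable day fractions in `[0, 1]`
#'   (vectorized).
#' @return ERI in `[0, 1]`.
#' @export
establishment_risk_index <- function(x_egg, x_larva, x_pupa) {
  xs <- cbind(x_egg, x_larva, x_pupa)
  if (any(xs < 0 | xs > 1, na.rm = TRUE))
    stop("non-survivable fractions must lie in [0, 1]")
  (1 - x_egg) * (1 - x_larva) * (1 - x_pupa)
}

#' Generation index
#'
#' Mean annualized generation count: `GI = mean(365 / Tx)` over the Julian
#' days of the year, with `Tx` the generation length (days) predicted for
#' day `x`.  Constant `Tx` gives exactly `365 / Tx` generations per year.
#'
#' @param Tx daily generation lengths, days, all positive (length 365 for a
#'   full year).
#' @return generations per year.
#' @export
generation_index <- function(Tx) {
  if (any(!is.finite(Tx)) || any(Tx <= 0))
    stop("all generation lengths must be positive and finite")
  mean(365 / Tx)
}

#' Activity index
#'
#' Log10 of the year's multiplicative population growth potential:
#' `AI = sum(log10(lambda_x))` over Julian days, with `lambda_x` the finite
#' daily rate of increase.  Days with `lambda < 1` contribute negative terms
#' (they are not floored), which keeps AI additive over sub-periods.  An AI
#' of 4 means a 10^4-fold potential increase within the year.
#'
#' @param lambda_x daily finite rates of increase, all positive.
#' @return the activity index (dimensionless, log10 scale).
#' @export
activity_index <- function(lambda_x) {
  if (any(!is.finite(lambda_x)) || any(lambda_x <= 0))
    stop("all daily rates must be positive and finite")
  sum(log10(lambda_x))
}

#' Risk-index configuration
#'
#' @param mortality_cutoff a day is non-survivable for a stage when the Wang
#'   mortality at the day's mean temperature exceeds this value (default
#'   0.99).
#' @param rate_zero_tol a day is also non-survivable when the development
#'   rate is at or below this value at every sub-daily step (default 0, i.e.
#'   exactly zero).
#' @return a list of class `risk_config`.
#' @export
risk_config <- function(mortality_cutoff = 0.99, rate_zero_tol = 0) {
  stopifnot(mortality_cutoff > 0, mortality_cutoff <= 1)
  structure(list(mortality_cutoff = mortality_cutoff,
                 rate_zero_tol = rate_zero_tol), class = "risk_config")
}

#' Risk indices for one location
#'
#' For each Julian day of a daily min/max series: the day's mean temperature
#' is the mean of the 96-step cosine profile; an immature stage is flagged
#' non-survivable when its Wang mortality at that mean exceeds the
#' configured cutoff or its development rate vanishes at every sub-daily
#' step; the generation length `Tx` and intrinsic rate come from the
#' quadratic parameter responses evaluated at the day mean (clipped, without
#' warning, to their fitted ranges); `lambda_x = exp(rm_x)`.  The three
#' indices then aggregate the 365 days.
#'
#' @param phenology a [phenology_model()] (for mortality and rate curves).
#' @param responses named list with `parameter_response` objects `T` (mean
#'   generation time, days) and `rm` (intrinsic rate, per day).
#' @param series a [temperature_series()] covering the year (only the first
#'   365 days are used; shorter series are an error).
#' @param config a [risk_config()].
#' @return a list with `ERI`, `GI`, `AI` and `detail` (per-day data frame).
#' @export
location_risk <- function(phenology, responses, series,
                          config = risk_config()) {
  stopifnot(inherits(series, "temperature_series"))
  if (!all(c("T", "rm") %in% names(responses)))
    stop("responses must contain parameter responses 'T' and 'rm'")
  ndays <- min(nrow(series), 365L)
  if (nrow(series) < 365L) stop("series must cover 365 days")
  profiles <- vapply(seq_len(ndays), daily_profile, numeric(96),
                     series = series)
  tbar <- colMeans(profiles)
  nonsurv <- sapply(.STAGES, function(s) {
    m <- eval_mortality(phenology$mortality[[s]], tbar)
    bad <- m > config$mortality_cutoff
    r <- matrix(eval_development_rate(phenology$dev_rate[[s]], profiles),
                nrow = 96)
    bad | apply(r <= config$rate_zero_tol, 2, all)
  })
  x_frac <- colMeans(nonsurv)
  clipq <- function(resp, tt) {
    tt <- pmin(pmax(tt, resp$range[1]), resp$range[2])
    resp$a + resp$b * tt + resp$c * tt^2
  }
  Tx <- pmax(clipq(responses$T, tbar), 1)
  rm_x <- clipq(responses$rm, tbar)
  lambda_x <- exp(rm_x)
  list(
    ERI = establishment_risk_index(x_frac[["egg"]], x_frac[["larva"]],
                                   x_frac[["pupa"]]),
    GI = generation_index(Tx),
    AI = activity_index(lambda_x),
    detail = data.frame(day = seq_len(ndays), tmean = tbar,
                        nonsurv_egg = nonsurv[, "egg"],
                        nonsurv_larva = nonsurv[, "larva"],
                        nonsurv_pupa = nonsurv[, "pupa"],
                        Tx = Tx, lambda = lambda_x))
}

#' Construct a risk grid
#'
#' A lightweight in-memory raster: named layer matrices sharing one
#' geometry.  Rows run north to south, columns west to east, matching the
#' ESRI ASCII grid layout.
#'
#' @param layers named list of numeric matrices with identical dimensions;
#'   `NA` cells are nodata.
#' @param geometry list with `xll`, `yll` (lower-left corner), `cellsize`
#'   and optionally `crs` (free-text tag).
#' @return an object of class `risk_grid`.
#' @export
risk_grid <- function(layers, geometry) {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)))
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L) stop("all layers must share dimensions")
  geometry$nrows <- nrow(layers[[1]])
  geometry$ncols <- ncol(layers[[1]])
  if (is.null(geometry$xll)) geometry$xll <- 0
  if (is.null(geometry$yll)) geometry$yll <- 0
  if (is.null(geometry$cellsize)) geometry$cellsize <- 1
  structure(list(layers = layers, geometry = geometry), class = "risk_grid")
}

#' @export
print.risk_grid <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("risk_grid: %d x %d cells (cellsize %g), layers: %s\n",
              g$nrows, g$ncols, g$cellsize,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

.same_geometry <- function(a, b) {
  ga <- a$geometry; gb <- b$geometry
  isTRUE(ga$nrows == gb$nrows) && isTRUE(ga$ncols == gb$ncols) &&
    isTRUE(all.equal(ga$xll, gb$xll)) && isTRUE(all.equal(ga$yll, gb$yll)) &&
    isTRUE(all.equal(ga$cellsize, gb$cellsize))
}

#' Risk indices over a gridded monthly climatology
#'
#' Per grid cell: the 12 monthly min/max pairs are expanded to a 365-day
#' series by [monthly_to_daily()] and fed to [location_risk()]; cells with
#' any missing month propagate nodata in all layers.  Deterministic given
#' its inputs and configuration.
#'
#' @param climate a `climate_stack` (see [generate_climate_raster()] or
#'   [read_climate_stack()]): geometry plus `tmin` and `tmax` arrays of
#'   dimension `nrows x ncols x 12`.
#' @param phenology a [phenology_model()].
#' @param responses as in [location_risk()].
#' @param config a [risk_config()].
#' @return a [risk_grid()] with layers `ERI`, `GI`, `AI`.
#' @export
grid_risk <- function(climate, phenology, responses, config = risk_config()) {
  stopifnot(inherits(climate, "climate_stack"))
  nr <- dim(climate$tmin)[1]; nc <- dim(climate$tmin)[2]
  ERI <- GI <- AI <- matrix(NA_real_, nr, nc)
  any_val <- FALSE
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      tmin <- climate$tmin[i, j, ]
      tmax <- climate$tmax[i, j, ]
      if (anyNA(tmin) || anyNA(tmax)) next
      lr <- location_risk(phenology, responses,
                          monthly_to_daily(data.frame(tmin = tmin,
                                                      tmax = tmax)),
                          config)
      ERI[i, j] <- lr$ERI; GI[i, j] <- lr$GI; AI[i, j] <- lr$AI
      any_val <- TRUE
    }
  }
  if (!any_val) stop("all cells are nodata")
  risk_grid(list(ERI = ERI, GI = GI, AI = AI), climate$geometry)
}

#' Change map between two risk grids
#'
#' Per-layer difference `future - baseline`; a cell that is nodata in either
#' input is nodata in the change.
#'
#' @param baseline,future [risk_grid()] objects with identical geometry and
#'   layer sets.
#' @return a [risk_grid()] with layers named `<layer>_change`.
#' @export
change_map <- function(baseline, future) {
  stopifnot(inherits(baseline, "risk_grid"), inherits(future, "risk_grid"))
  if (!.same_geometry(baseline, future)) stop("grid geometry mismatch")
  if (!setequal(names(baseline$layers), names(future$layers)))
    stop("layer sets differ")
  out <- lapply(names(baseline$layers), function(nm)
    future$layers[[nm]] - baseline$layers[[nm]])
  names(out) <- paste0(names(baseline$layers), "_change")
  risk_grid(out, baseline$geometry)
}

#' Mask a risk grid
#'
#' Cells outside the mask become nodata in every layer.  The mask is a 0/1
#' (or logical) matrix or a single-layer [risk_grid()] on the same geometry;
#' 0/`FALSE`/`NA` cells are outside.
#'
#' @param grid a [risk_grid()].
#' @param mask matrix or single-layer `risk_grid`.
#' @return the masked [risk_grid()].  A mask that removes every cell
#'   triggers a warning and returns a fully masked grid.
#' @export
apply_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "risk_grid"))
  if (inherits(mask, "risk_grid")) {
    if (!.same_geometry(grid, mask)) stop("mask geometry mismatch")
    mask <- mask$layers[[1]]
  }
  if (!all(dim(mask) == c(grid$geometry$nrows, grid$geometry$ncols)))
    stop("mask dimensions do not match grid")
  keep <- !is.na(mask) & mask != 0
  if (!any(keep))
    warning("mask retains no cells; returning a fully masked grid")
  out <- lapply(grid$layers, function(L) { L[!keep] <- NA_real_; L })
  risk_grid(out, grid$geometry)
}
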