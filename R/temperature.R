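#' Daily minimum/maximum temperature series
#'
#' @param dates integer day index (Julian days or consecutive dates); must be
#'   gap-free and strictly increasing.
#' @param tmin,tmax daily minimum and maximum temperatures, degrees C, with
#'   `tmin <= tmax` elementwise.
#' @return a data frame of class `temperature_series` with columns `day`,
#'   `tmin`, `tmax`.
#' @export
temperature_series <- function(dates, tmin, tmax) {
  dates <- as.integer(dates)
  stopifnot(length(dates) == length(tmin), length(tmin) == length(tmax))
  if (length(dates) == 0L) stop("empty series")
  if (any(diff(dates) != 1L)) stop("date index must be gap-free")
  if (any(tmin > tmax)) stop("tmin must not exceed tmax")
  structure(data.frame(day = dates, tmin = tmin, tmax = tmax),
            class = c("temperature_series", "data.frame"))
}

#' Read a daily weather CSV
#'
#' Columns: `date` (ISO 8601 or integer day-of-year), `tmin_c`, `tmax_c`.
#'
#' @param path CSV file path.
#' @return a [temperature_series()].
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c")
  if (!all(need %in% names(df)))
    stop("weather CSV must have columns: ", paste(need, collapse = ", "))
  d <- df$date
  if (is.character(d)) d <- as.integer(as.Date(d) - as.Date(d[1])) + 1L
  temperature_series(d, df$tmin_c, df$tmax_c)
}

#' Cosine half-day temperature interpolation
#'
#' Temperature of 15-minute step `i` (1..48) within one half day, sweeping
#' from the daily maximum down to the daily minimum over one half cosine
#' period:
#' \deqn{T_i = \frac{Max-Min}{2}\cos\left(\frac{\pi(i-0.5)}{48}\right)
#'   + \frac{Min+Max}{2}}
#'
#' @param min_c,max_c half-day minimum and maximum, degrees C.
#' @param i step index, 1..48 (vectorized).
#' @return temperature at each step, degrees C.
#' @export
halfday_temperature <- function(min_c, max_c, i) {
  if (any(i < 1 | i > 48)) stop("'i' must lie in 1..48")
  if (min_c > max_c) stop("min_c must not exceed max_c")
  (max_c - min_c) / 2 * cos(pi * (i - 0.5) / 48) + (min_c + max_c) / 2
}

#' Sub-daily temperature profile for one day
#'
#' Expands one day of a [temperature_series()] into 96 15-minute steps: the
#' first 48 steps run the cosine from the day's maximum down to the day's
#' minimum, the second 48 repeat the cosine using the *next* day's minimum
#' (so step 96 lands on the following morning's minimum).  The final day of
#' the series reuses its own minimum.
#'
#' @param day row index into the series.
#' @param series a [temperature_series()].
#' @return numeric vector of 96 temperatures, degrees C.
#' @export
daily_profile <- function(day, series) {
  stopifnot(inherits(series, "temperature_series"))
  n <- nrow(series)
  if (n == 0L) stop("empty series")
  if (day < 1 || day > n) stop("day out of range")
  nxt <- if (day < n) day + 1L else day
  i <- 1:48
  c(halfday_temperature(series$tmin[day], series$tmax[day], i),
    halfday_temperature(min(series$tmin[nxt], series$tmax[day]),
                        series$tmax[day], i))
}

# month lengths of the 365-day model year and the anchor day of each month
# (the day whose interpolated value equals the monthly input exactly)
.MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_MID <- cumsum(.MONTH_LEN) - .MONTH_LEN %/% 2L

#' Expand a monthly climatology to a daily temperature series
#'
#' Linear interpolation between month-midpoint anchors over a 365-day year,
#' wrapping December to January, so the value on each month's anchor day
#' equals the monthly input exactly and monthly means track the inputs
#' closely.
#'
#' @param climatology a data frame (or 12 x 2 matrix) with columns `tmin`,
#'   `tmax`: one row per month, January first, `tmin <= tmax`.
#' @return a 365-day [temperature_series()].
#' @export
monthly_to_daily <- function(climatology) {
  cl <- as.data.frame(climatology)
  if (!all(c("tmin", "tmax") %in% names(cl))) {
    if (ncol(cl) == 2L) names(cl) <- c("tmin", "tmax")
    else stop("climatology must have columns tmin, tmax")
  }
  if (nrow(cl) != 12L) stop("climatology must have 12 monthly rows")
  if (any(cl$tmin > cl$tmax)) stop("tmin must not exceed tmax")
  interp <- function(v) {
    x <- c(.MONTH_MID[12] - 365, .MONTH_MID, .MONTH_MID[1] + 365)
    yv <- c(v[12], v, v[1])
    stats::approx(x, yv, xout = 1:365)$y
  }
  temperature_series(1:365, interp(cl$tmin), interp(cl$tmax))
}
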