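#' Season window between phenological events
#'
#' @param bloom full-bloom date (ISO-8601 string or `Date`).
#' @param harvest harvest date (ISO-8601 string or `Date`).
#' @return list with `bloom` and `harvest` as `Date`, class `season_window`.
#' @export
season_window <- function(bloom, harvest) {
  bloom <- as.Date(bloom)
  harvest <- as.Date(harvest)
  if (is.na(bloom) || is.na(harvest)) stop("dates must parse as ISO-8601")
  if (!bloom < harvest) stop("bloom date must precede harvest date")
  structure(list(bloom = bloom, harvest = harvest), class = "season_window")
}

#' Growing degree-day configuration
#'
#' Defaults follow the peach convention: base and lower threshold of 7 deg C
#' (growth trigger) and an upper threshold of 35 deg C (growth ceases above).
#' Under these defaults the daily Method-2 term lies in \[0, 28\].
#'
#' @param Tbase base temperature (deg C) subtracted from the daily mean.
#' @param TLT lower threshold temperature (deg C) for Method 2 clamping.
#' @param TUT upper threshold temperature (deg C) for Method 2 clamping.
#' @return list of class `gdd_config`.
#' @export
gdd_config <- function(Tbase = 7, TLT = 7, TUT = 35) {
  if (TLT > TUT) stop("TLT must not exceed TUT")
  structure(list(Tbase = Tbase, TLT = TLT, TUT = TUT), class = "gdd_config")
}

# Slice a daily series to the inclusive bloom..harvest window, checking that
# every calendar day is present.
.window_slice <- function(daily, window) {
  stopifnot(inherits(window, "season_window"))
  daily <- as.data.frame(daily)
  if (!all(c("date") %in% names(daily))) stop("daily series needs a 'date' column")
  dates <- as.Date(daily$date)
  wanted <- seq(window$bloom, window$harvest, by = "day")
  idx <- match(wanted, dates)
  if (anyNA(idx)) {
    gaps <- wanted[is.na(idx)]
    stop("daily series does not cover the window; missing days: ",
         paste(utils::head(gaps, 5), collapse = ", "),
         if (length(gaps) > 5) sprintf(" (and %d more)", length(gaps) - 5) else "")
  }
  daily[idx, , drop = FALSE]
}

#' Cumulative growing degree-days, Method 1
#'
#' Sums `(Tmin + Tmax)/2 - Tbase` over every day from bloom to harvest
#' (inclusive). Daily terms are not clamped, so cold days can contribute
#' negative degree-days; that is the defining difference from Method 2.
#'
#' @param daily data.frame with columns `date`, `tmin`, `tmax` (deg C).
#' @param window a [season_window()].
#' @param cfg a [gdd_config()].
#' @return cumulative degree-days (scalar).
#' @export
gdd_method1 <- function(daily, window, cfg = gdd_config()) {
  d <- .window_slice(daily, window)
  sum((d$tmin + d$tmax) / 2 - cfg$Tbase)
}

#' Cumulative growing degree-days, Method 2 (threshold-clamped)
#'
#' As Method 1, but each day's Tmin and Tmax are independently clamped into
#' `[TLT, TUT]` before averaging. With the default configuration every daily
#' term lies in \[0, 28\]: a day entirely at or above 35 deg C contributes 28
#' degree-days, a 7/7 deg C day contributes zero.
#'
#' @inheritParams gdd_method1
#' @return cumulative degree-days (scalar).
#' @export
gdd_method2 <- function(daily, window, cfg = gdd_config()) {
  d <- .window_slice(daily, window)
  tmin <- pmin(pmax(d$tmin, cfg$TLT), cfg$TUT)
  tmax <- pmin(pmax(d$tmax, cfg$TLT), cfg$TUT)
  sum((tmin + tmax) / 2 - cfg$Tbase)
}

#' Daily cumulative degree-day series for both methods
#'
#' Used to compare the two accumulation methods along a season.
#'
#' @inheritParams gdd_method1
#' @return data.frame with `date`, `gdd1`, `gdd2` (running totals).
#' @export
gdd_cumulative <- function(daily, window, cfg = gdd_config()) {
  d <- .window_slice(daily, window)
  t1 <- (d$tmin + d$tmax) / 2 - cfg$Tbase
  tmin <- pmin(pmax(d$tmin, cfg$TLT), cfg$TUT)
  tmax <- pmin(pmax(d$tmax, cfg$TLT), cfg$TUT)
  t2 <- (tmin + tmax) / 2 - cfg$Tbase
  data.frame(date = as.Date(d$date), gdd1 = cumsum(t1), gdd2 = cumsum(t2))
}

#' Chilling hours
#'
#' Counts hours with air temperature below the threshold (Weinberger
#' convention, 7.2 deg C) over a window, typically the autumn-winter dormant
#' season. Fewer chilling hours mean a warmer winter and incomplete dormancy
#' release in temperate fruit trees.
#'
#' @param hourly data.frame with columns `datetime` (POSIXct or parseable)
#'   and `temp` (deg C).
#' @param window optional [season_window()]; when `NULL` the whole series is
#'   used.
#' @param threshold temperature threshold in deg C.
#' @return integer count of hours below `threshold`.
#' @export
chilling_hours <- function(hourly, window = NULL, threshold = 7.2) {
  hourly <- as.data.frame(hourly)
  tt <- as.POSIXct(hourly$datetime, tz = "UTC")
  if (!is.null(window)) {
    stopifnot(inherits(window, "season_window"))
    keep <- as.Date(tt) >= window$bloom & as.Date(tt) <= window$harvest
    if (!any(keep)) stop("hourly series has no observations in the window")
    hourly <- hourly[keep, , drop = FALSE]
  }
  if (!nrow(hourly)) stop("empty hourly series")
  sum(hourly$temp < threshold)
}

#' Cumulative rainfall over a season window
#'
#' @param daily data.frame with columns `date` and `rain` (mm).
#' @param window a [season_window()].
#' @return total rainfall in mm.
#' @export
season_rainfall <- function(daily, window) {
  d <- .window_slice(daily, window)
  if (any(d$rain < 0)) stop("negative rainfall values in series")
  sum(d$rain)
}

#' Per-season climate indices
#'
#' Convenience wrapper computing, for each cropping season, GDD1 and GDD2
#' between bloom and harvest, cumulative rainfall over the same window, and
#' chilling hours over the dormant season (May 1 to August 31 of the harvest
#' year; Southern-Hemisphere autumn-winter).
#'
#' @param weather a `weather_sim` object or list with `daily` and `hourly`
#'   data.frames (see [simulate_weather()] / [read_weather()]).
#' @param windows named list of [season_window()]s, one per season label.
#' @param cfg a [gdd_config()].
#' @param chill_threshold chilling-hour threshold in deg C.
#' @return data.frame with one row per season: `year`, `gdd1`, `gdd2`,
#'   `rain_mm`, `chill_h`.
#' @export
climate_summary <- function(weather, windows, cfg = gdd_config(),
                            chill_threshold = 7.2) {
  out <- lapply(names(windows), function(yr) {
    w <- windows[[yr]]
    dorm <- season_window(paste0(yr, "-05-01"), paste0(yr, "-08-31"))
    data.frame(
      year = as.integer(yr),
      gdd1 = gdd_method1(weather$daily, w, cfg),
      gdd2 = gdd_method2(weather$daily, w, cfg),
      rain_mm = season_rainfall(weather$daily, w),
      chill_h = chilling_hours(weather$hourly, dorm, chill_threshold))
  })
  do.call(rbind, out)
}

#' Read daily and hourly weather series
#'
#' Daily files need columns `date,tmin,tmax,rain`; hourly files need
#' `datetime,temp`. Comma-separated, "." decimal.
#'
#' @param daily_path path to the daily CSV.
#' @param hourly_path optional path to the hourly CSV.
#' @return list with `daily` (and `hourly` if supplied), class `weather_sim`.
#' @export
read_weather <- function(daily_path, hourly_path = NULL) {
  daily <- utils::read.csv(daily_path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "rain")
  if (!all(need %in% names(daily)))
    stop("daily weather needs columns: ", paste(need, collapse = ", "))
  daily$date <- as.Date(daily$date)
  out <- list(daily = daily)
  if (!is.null(hourly_path)) {
    hourly <- utils::read.csv(hourly_path, stringsAsFactors = FALSE)
    if (!all(c("datetime", "temp") %in% names(hourly)))
      stop("hourly weather needs columns: datetime, temp")
    hourly$datetime <- as.POSIXct(hourly$datetime, tz = "UTC")
    out$hourly <- hourly
  }
  structure(out, class = "weather_sim")
}
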