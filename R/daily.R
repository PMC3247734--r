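# Daily weather summaries, including the vapor pressure deficit chain.
#
# VPD is computed half-hourly and then averaged over the day; because the
# saturation curve is nonlinear, this differs from the VPD of daily-mean
# inputs, and the half-hourly-first ordering is deliberate.

#' Saturation vapor pressure
#'
#' Magnus-type saturation vapor pressure over water,
#' `SVP = 6.11 * exp(17.2693882 * AT / (AT + 237.3))` (hPa), strictly
#' increasing in air temperature.
#'
#' @param at air temperature (C), must exceed -237.3.
#' @return saturation vapor pressure (hPa).
#' @export
svp <- function(at) {
  if (any(!is.na(at) & at <= -237.3)) {
    stop("air temperature outside the domain of the saturation formula (> -237.3 C)")
  }
  6.11 * exp(17.2693882 * at / (at + 237.3))
}

#' Ambient vapor pressure
#'
#' `VP = RH * SVP * P / (RH * SVP + 100 * (P - SVP))` (hPa), from relative
#' humidity, saturation vapor pressure and barometric pressure. Equals `SVP`
#' at RH = 100 and 0 at RH = 0.
#'
#' @param svp_val saturation vapor pressure (hPa), positive.
#' @param rh relative humidity (%), in [0, 100].
#' @param p barometric pressure (hPa), must exceed `svp_val`.
#' @return ambient vapor pressure (hPa), in [0, `svp_val`].
#' @export
vp <- function(svp_val, rh, p) {
  ok <- !is.na(svp_val) & !is.na(rh) & !is.na(p)
  if (any(ok & (rh < 0 | rh > 100))) stop("rh must lie in [0, 100]")
  if (any(ok & p <= svp_val)) {
    stop("pressure must exceed saturation vapor pressure (degenerate denominator)")
  }
  rh * svp_val * p / (rh * svp_val + 100 * (p - svp_val))
}

#' Half-hourly vapor pressure deficit
#'
#' `VPD = SVP(tair) - VP(SVP, rh, pressure)` (hPa); zero at saturation,
#' missing whenever any input is missing.
#'
#' @param tair air temperature (C).
#' @param rh relative humidity (%).
#' @param pressure barometric pressure (hPa).
#' @return vapor pressure deficit (hPa), >= 0.
#' @export
vpd_halfhourly <- function(tair, rh, pressure) {
  s <- svp(tair)
  out <- s - vp(s, rh, pressure)
  out[is.na(tair) | is.na(rh) | is.na(pressure)] <- NA_real_
  pmax(0, out)
}

#' Collapse half-hourly weather to daily summaries
#'
#' Builds the twelve daily explanatory variables: totals for precipitation and
#' solar radiation, extremes for air/soil temperature and wind gust, means for
#' soil moisture, relative humidity, pressure and wind speed, and the daily
#' mean of the half-hourly vapor pressure deficit. Totals/extremes/means are
#' taken over present slots; a day with slot coverage below
#' `coverage_threshold` is retained as a row but all its summaries are set
#' missing. An empty day yields missing values, never zeros.
#'
#' @param records half-hourly weather data.frame (as from [generate_weather()]
#'   or [read_logger()]).
#' @param coverage_threshold minimum fraction of the 48 slots that must be
#'   present (default 0.75).
#' @return data.frame with one row per date: `date`, `prec_total`,
#'   `tair_max`, `tair_min`, `tsoil_max`, `tsoil_min`, `soil_moisture_mean`,
#'   `rh_mean`, `pressure_mean`, `solrad_total`, `wind_speed_mean`,
#'   `wind_gust_max`, `vpd_mean`, `coverage`.
#' @export
daily_weather <- function(records, coverage_threshold = 0.75) {
  dt <- data.table::as.data.table(records)
  dt[, date := grid_date(timestamp)]
  dt[, vpd := vpd_halfhourly(tair, rh, pressure)]
  chan <- intersect(WEATHER_CHANNELS, names(dt))
  present <- rowSums(!is.na(as.data.frame(dt)[chan])) > 0
  dt[, present := present]
  daily <- dt[, .(
    coverage = sum(present) / SLOTS_PER_DAY,
    prec_total = sum_na(precip),
    tair_max = max_na(tair), tair_min = min_na(tair),
    tsoil_max = max_na(tsoil), tsoil_min = min_na(tsoil),
    soil_moisture_mean = mean_na(soil_moisture),
    rh_mean = mean_na(rh),
    pressure_mean = mean_na(pressure),
    solrad_total = sum_na(solrad),
    wind_speed_mean = mean_na(wind_speed),
    wind_gust_max = max_na(wind_gust),
    vpd_mean = mean_na(vpd)
  ), by = date]
  daily <- as.data.frame(daily[order(date)])
  low <- daily$coverage < coverage_threshold
  meas <- setdiff(names(daily), c("date", "coverage"))
  daily[low, meas] <- NA_real_
  daily
}

#' Monthly climatology of daily summaries
#'
#' Per calendar month across years: mean monthly totals for precipitation and
#' solar radiation (sum of valid days within each year-month, averaged across
#' years) and means of the remaining daily summaries. A calendar month with no
#' retained days in any year is missing.
#'
#' @param daily output of [daily_weather()].
#' @return data.frame with one row per calendar month (1-12): `month`,
#'   `prec_total`, `solrad_total` (mean monthly totals) and means of the other
#'   summaries, plus `n_years` (year-months contributing).
#' @export
monthly_climatology <- function(daily) {
  dt <- data.table::as.data.table(daily)
  dt[, `:=`(year = as.POSIXlt(date)$year + 1900L,
            month = as.POSIXlt(date)$mon + 1L)]
  valid <- dt[!is.na(tair_max)]
  ym <- valid[, .(
    prec_total = sum_na(prec_total),
    solrad_total = sum_na(solrad_total),
    tair_max = mean_na(tair_max), tair_min = mean_na(tair_min),
    tair_mean = mean_na((tair_max + tair_min) / 2),
    tsoil_max = mean_na(tsoil_max), tsoil_min = mean_na(tsoil_min),
    tsoil_mean = mean_na((tsoil_max + tsoil_min) / 2),
    soil_moisture_mean = mean_na(soil_moisture_mean),
    rh_mean = mean_na(rh_mean),
    pressure_mean = mean_na(pressure_mean),
    wind_speed_mean = mean_na(wind_speed_mean),
    wind_gust_max = mean_na(wind_gust_max),
    vpd_mean = mean_na(vpd_mean)
  ), by = .(year, month)]
  clim <- ym[, lapply(.SD, mean_na), by = month,
             .SDcols = setdiff(names(ym), c("year", "month"))]
  counts <- ym[, .(n_years = .N), by = month]
  clim <- merge(as.data.frame(clim), as.data.frame(counts),
                by = "month", all.x = TRUE)
  out <- merge(data.frame(month = 1:12), clim, by = "month", all.x = TRUE)
  out[order(out$month), ]
}
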