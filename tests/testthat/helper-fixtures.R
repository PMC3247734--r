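# Small in-code fixtures shared across the suite.

# one noise-free constant day of weather on the half-hour grid
constant_weather_day <- function(date = "2002-06-01", tair = 5, rh = 60,
                                 pressure = 645, precip = 0) {
  ts <- half_hour_grid(date, 1)
  data.frame(timestamp = ts, precip = precip, tair = tair, tsoil = tair,
             soil_moisture = 20, rh = rh, pressure = pressure,
             solrad = 0.2, wind_speed = 5, wind_gust = 8)
}

# a fast small climate/stem pair for pipeline-level tests
small_stem_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_trees = 2, sri_noise_sd = 0, diel_amplitude = 0, tree_spread_sd = 0,
         climate_sensitivity = list(spring_tsoil = 0, monsoon_precip = 0)),
    list(...))
  do.call(stem_config, args)
}

# daily-max frame for a single tree
dm_frame <- function(day_max, start = "2002-05-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = length(day_max)),
             site_id = "S1", tree_id = "T01", day_max = day_max)
}

# brute-force SRI oracle: literal day-by-day application of the rules
sri_oracle <- function(day_max, threshold = 350) {
  out <- rep(NA_real_, length(day_max))
  for (i in seq_along(day_max)[-1]) {
    cur <- day_max[i]; prev <- day_max[i - 1]
    if (is.na(cur) || is.na(prev)) next
    d <- cur - prev
    if (d > threshold) next          # spurious -> missing
    out[i] <- max(d, 0)              # negative differences floor to zero
  }
  out
}
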