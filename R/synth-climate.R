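# Synthetic half-hourly weather for a tropical treeline monsoon regime.
#
# The default configuration is calibrated to the instrumented ridge on Nevado
# de Colima (~3,760 m a.s.l., 19.6 N): ~1,220 mm mean annual rainfall with
# ~85% falling June-October, September the wettest month (~277 mm) and April
# the driest (~8 mm), annual mean air temperature ~6.6 C (May warmest, January
# coldest), damped soil temperatures staying above 3.5 C in winter, relative
# humidity peaking in September, and insolation peaking in spring before the
# monsoon clouds arrive.

.default_monthly <- list(
  #           Jan   Feb   Mar   Apr   May   Jun   Jul   Aug   Sep   Oct   Nov   Dec
  precip  = c(  30,   20,   12,    8,   35,  215,  235,  225,  277,   85,   45,   33),
  tair    = c( 4.2,  4.8,  6.0,  7.4,  8.4,  8.0,  7.6,  7.5,  7.2,  6.8,  5.8,  4.8),
  tair_hr = c( 5.1,  5.2,  5.5,  5.5,  5.4,  4.2,  3.8,  3.8,  3.6,  4.2,  5.0,  5.1),
  tsoil   = c( 3.9,  3.9,  5.5,  8.0, 10.5, 12.5, 13.0, 13.0, 12.5, 10.5,  6.5,  4.4),
  rh      = c(  52,   50,   48,   52,   58,   74,   78,   80,   84,   72,   58,   54),
  swv     = c(  18,   17,   16,   15,   14,   20,   23,   24,   24,   22,   20,   19),
  solrad  = c(  18,   21, 26.5, 24.5, 23.5,   17,   15,   14,   13,   16,   17,   16),
  wet_p   = c(0.010, 0.008, 0.006, 0.005, 0.012, 0.070, 0.080, 0.080, 0.090, 0.035, 0.015, 0.010)
)

#' Climate generator configuration
#'
#' Parameters of the synthetic half-hourly weather generator. Defaults encode
#' the study-area climate regime (monsoon-season rainfall share ~85%, annual
#' total ~1,220 mm, annual mean air temperature ~6.6 C).
#'
#' @param monthly_precip_mm twelve mean monthly precipitation totals (mm).
#' @param monthly_tair_mean twelve monthly mean air temperatures (C).
#' @param monthly_tair_halfrange twelve monthly half diurnal ranges (C);
#'   monthly mean daily maximum ~ mean + halfrange, minimum ~ mean - halfrange.
#' @param monthly_tsoil_mean twelve monthly mean soil temperatures at ~30 cm
#'   depth (C); damped and seasonally lagged relative to air temperature.
#' @param monthly_rh_mean twelve monthly mean relative humidities (%).
#' @param monthly_swv_mean twelve monthly mean volumetric soil moistures (%).
#' @param monthly_solrad twelve monthly mean daily insolation totals
#'   (MJ m-2 day-1).
#' @param pressure_mean mean barometric pressure (hPa) at station elevation.
#' @param wind_mean mean half-hourly wind speed (km hr-1).
#' @param precip_event_model list with `wet_prob` (twelve per-slot occurrence
#'   probabilities), `gamma_shape` (event intensity shape), `annual_sdlog` and
#'   `monthly_sdlog` (log-sd of the yearly monsoon-strength factor and of the
#'   per-month jitter that create interannual variability).
#' @param tair_interannual_sd sd (C) of the yearly air-temperature offset.
#' @param soil_smooth_alpha exponential-smoothing constant transferring the
#'   half-hourly air-temperature anomaly into soil temperature (0..1; higher =
#'   more damping).
#' @param soil_anomaly_damping multiplier applied to the smoothed air anomaly
#'   before adding it to the seasonal soil baseline (buffers day-to-day soil
#'   swings relative to air swings).
#' @param seed integer seed; every random draw in [generate_weather()] flows
#'   from it.
#' @return object of class `climate_config` (a validated list).
#' @seealso [generate_weather()]
#' @export
climate_config <- function(monthly_precip_mm = .default_monthly$precip,
                           monthly_tair_mean = .default_monthly$tair,
                           monthly_tair_halfrange = .default_monthly$tair_hr,
                           monthly_tsoil_mean = .default_monthly$tsoil,
                           monthly_rh_mean = .default_monthly$rh,
                           monthly_swv_mean = .default_monthly$swv,
                           monthly_solrad = .default_monthly$solrad,
                           pressure_mean = 645,
                           wind_mean = 10,
                           precip_event_model = list(
                             wet_prob = .default_monthly$wet_p,
                             gamma_shape = 1.5,
                             annual_sdlog = 0.07,
                             monthly_sdlog = 0.03),
                           tair_interannual_sd = 0.25,
                           soil_smooth_alpha = 0.955,
                           soil_anomaly_damping = 0.6,
                           seed = 1L) {
  cfg <- list(monthly_precip_mm = monthly_precip_mm,
              monthly_tair_mean = monthly_tair_mean,
              monthly_tair_halfrange = monthly_tair_halfrange,
              monthly_tsoil_mean = monthly_tsoil_mean,
              monthly_rh_mean = monthly_rh_mean,
              monthly_swv_mean = monthly_swv_mean,
              monthly_solrad = monthly_solrad,
              pressure_mean = pressure_mean,
              wind_mean = wind_mean,
              precip_event_model = precip_event_model,
              tair_interannual_sd = tair_interannual_sd,
              soil_smooth_alpha = soil_smooth_alpha,
              soil_anomaly_damping = soil_anomaly_damping,
              seed = seed)
  validate_climate_config(cfg)
  class(cfg) <- "climate_config"
  cfg
}

validate_climate_config <- function(cfg) {
  twelve <- c("monthly_precip_mm", "monthly_tair_mean", "monthly_tair_halfrange",
              "monthly_tsoil_mean", "monthly_rh_mean", "monthly_swv_mean",
              "monthly_solrad")
  for (f in twelve) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 12 || anyNA(v)) {
      stop_invalid(f, "must be 12 non-missing numeric monthly values")
    }
  }
  if (any(cfg$monthly_precip_mm < 0)) {
    stop_invalid("monthly_precip_mm", "monthly precipitation means must be >= 0")
  }
  if (any(cfg$monthly_rh_mean < 0 | cfg$monthly_rh_mean > 100)) {
    stop_invalid("monthly_rh_mean", "relative humidity must lie in [0, 100]")
  }
  if (any(cfg$monthly_solrad < 0)) {
    stop_invalid("monthly_solrad", "insolation must be >= 0")
  }
  pem <- cfg$precip_event_model
  if (!is.list(pem) || length(pem$wet_prob) != 12 ||
      any(pem$wet_prob < 0 | pem$wet_prob > 1)) {
    stop_invalid("precip_event_model", "wet_prob must be 12 probabilities in [0, 1]")
  }
  if (cfg$soil_smooth_alpha <= 0 || cfg$soil_smooth_alpha >= 1) {
    stop_invalid("soil_smooth_alpha", "must lie strictly in (0, 1)")
  }
  invisible(cfg)
}

#' Generate synthetic half-hourly weather
#'
#' Simulates a continuous half-hourly weather record with monsoon seasonality:
#' Bernoulli-gamma precipitation with monthly occurrence/intensity parameters
#' scaled by a yearly monsoon-strength factor, diel cycles in air temperature
#' and solar radiation, soil temperature as an exponentially smoothed (damped)
#' transform of the air-temperature anomaly over a seasonal soil baseline,
#' relative humidity anti-phased with the afternoon temperature peak, a
#' precipitation-driven soil-moisture bucket, and gamma-distributed wind with
#' gusts. Deterministic under a fixed seed.
#'
#' @param config a [climate_config()].
#' @param years number of complete calendar years to simulate (>= 1).
#' @param start_year first simulated calendar year.
#' @param seed overrides `config$seed` when given.
#' @return data.frame with one row per half-hour slot and columns
#'   `timestamp`, `precip` (mm per interval), `tair`, `tsoil` (C),
#'   `soil_moisture` (%), `rh` (%), `pressure` (hPa), `solrad` (MJ m-2 per
#'   interval), `wind_speed`, `wind_gust` (km hr-1).
#' @export
generate_weather <- function(config = climate_config(), years = 1,
                             start_year = 2002, seed = config$seed) {
  if (!inherits(config, "climate_config")) validate_climate_config(config)
  if (years < 1) stop("years must be >= 1")
  with_seed(seed, {
    start <- as.Date(sprintf("%d-01-01", start_year))
    end <- as.Date(sprintf("%d-12-31", start_year + years - 1))
    dates <- seq(start, end, by = "day")
    n_days <- length(dates)
    ts <- half_hour_grid(start, n_days)
    doy <- as.POSIXlt(dates)$yday + 1
    mon <- as.POSIXlt(dates)$mon + 1
    yr_idx <- as.POSIXlt(dates)$year - as.POSIXlt(start)$year + 1
    n_years <- max(yr_idx)

    # interannual factors: one monsoon-strength factor per year scaling all
    # monthly rain intensities together, plus small independent month jitter
    pem <- config$precip_event_model
    sa <- pem$annual_sdlog; sm <- pem$monthly_sdlog
    wet_year <- stats::rlnorm(n_years, meanlog = -sa^2 / 2, sdlog = sa)
    jit_month <- matrix(stats::rlnorm(n_years * 12, -sm^2 / 2, sm), n_years, 12)
    tair_year <- stats::rnorm(n_years, 0, config$tair_interannual_sd)

    # daily latent anomalies: temperature (persistent) and cloudiness/wetness
    aT <- ar1(n_days, rho = 0.7, sd = 1.0) + tair_year[yr_idx]
    aC <- ar1(n_days, rho = 0.3, sd = 1.0)

    # seasonal baselines on the day-of-year scale
    s_tair <- monthly_to_doy(config$monthly_tair_mean, doy)
    s_amp  <- monthly_to_doy(config$monthly_tair_halfrange, doy)
    s_tsoil <- monthly_to_doy(config$monthly_tsoil_mean, doy)
    s_rh   <- monthly_to_doy(config$monthly_rh_mean, doy)
    s_swv  <- monthly_to_doy(config$monthly_swv_mean, doy)
    s_sol  <- monthly_to_doy(config$monthly_solrad, doy)

    n <- n_days * SLOTS_PER_DAY
    day_of <- rep(seq_len(n_days), each = SLOTS_PER_DAY)
    h <- rep(seq(0, 23.5, by = 0.5), n_days)
    shape_t <- cos(2 * pi * (h - 14) / 24)  # afternoon maximum, pre-dawn minimum

    tair <- s_tair[day_of] + aT[day_of] + s_amp[day_of] * shape_t +
      stats::rnorm(n, 0, 0.3)

    # soil temperature: seasonal baseline + damped smoothing of the air anomaly
    alpha <- config$soil_smooth_alpha
    anom <- tair - s_tair[day_of]
    smoothed <- as.numeric(stats::filter((1 - alpha) * anom, alpha,
                                         method = "recursive"))
    tsoil <- s_tsoil[day_of] + config$soil_anomaly_damping * smoothed +
      stats::rnorm(n, 0, 0.05)

    # precipitation: per-slot Bernoulli occurrence (cloudier days wetter) with
    # gamma intensities whose monthly means reproduce the monthly climatology
    ndays_m <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    occ_mult <- pmin(4, exp(0.35 * aC - 0.06125))
    p_slot <- pmin(0.5, pem$wet_prob[mon[day_of]] * occ_mult[day_of])
    mu_m <- ifelse(pem$wet_prob > 0,
                   config$monthly_precip_mm / (ndays_m * SLOTS_PER_DAY * pem$wet_prob),
                   0)
    inten_scale <- mu_m[mon[day_of]] *
      (wet_year[yr_idx] * jit_month[cbind(yr_idx, mon)])[day_of] / pem$gamma_shape
    wet <- stats::runif(n) < p_slot
    precip <- numeric(n)
    nw <- sum(wet)
    if (nw > 0) {
      precip[wet] <- stats::rgamma(nw, shape = pem$gamma_shape) * inten_scale[wet]
    }

    # solar radiation: daylight sine weights scaled by a cloudiness factor
    w_sol <- pmax(0, sin(pi * (h - 6) / 12))
    w_sol <- w_sol / sum(w_sol[seq_len(SLOTS_PER_DAY)])
    f_cloud <- exp(-0.3 * aC - 0.045)  # mean-one lognormal in the cloud anomaly
    solrad <- s_sol[day_of] * f_cloud[day_of] * w_sol

    rh <- s_rh[day_of] + 7 * aC[day_of] - 12 * shape_t + stats::rnorm(n, 0, 3)
    rh <- pmin(100, pmax(3, rh))

    # soil moisture: seasonal baseline + smoothed precipitation anomaly
    prec_day <- rowsum(precip, day_of)[, 1]
    exp_day <- config$monthly_precip_mm[mon] / ndays_m[mon]
    pa <- (prec_day - exp_day) / 10
    f_wet <- as.numeric(stats::filter(0.15 * pa, 0.85, method = "recursive"))
    swv <- s_swv[day_of] + 4 * f_wet[day_of] + stats::rnorm(n, 0, 0.3)
    swv <- pmin(50, pmax(3, swv))

    aP <- ar1(n_days, rho = 0.8, sd = 1.0)
    pressure <- config$pressure_mean + 1.2 * sin(2 * pi * (doy[day_of] - 15) / 365.25) +
      aP[day_of] + stats::rnorm(n, 0, 0.2)

    wind_speed <- stats::rgamma(n, shape = 2, scale = config$wind_mean / 2) *
      (1 + 0.25 * shape_t)
    wind_speed <- pmax(0, wind_speed)
    wind_gust <- wind_speed + stats::rgamma(n, shape = 1.2, scale = 6)

    data.frame(timestamp = ts, precip = precip, tair = tair, tsoil = tsoil,
               soil_moisture = swv, rh = rh, pressure = pressure,
               solrad = solrad, wind_speed = wind_speed, wind_gust = wind_gust)
  })
}
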