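# Synthetic point-dendrometer series: seasonal true increment + diel cycle
# + sensor noise, with ground truth emitted on a separate channel.
#
# Construction guarantees that, with noise off, each day's maximum stem size
# equals the baseline plus the cumulative true increment through that day:
# growth accrues from midnight and is complete by the diel maximum (~11:30,
# the end of the nocturnal-recharge/morning-photosynthesis expansion), and the
# diel term has a fixed amplitude, so day-over-day differences of daily maxima
# recover the true daily increment exactly.

#' Default seasonal growth-rate curve
#'
#' Skewed-Gaussian daily true-increment rate by day of year: a sharp spring
#' rise to a May peak and a slower decay through the monsoon, over a small
#' year-round base rate (moisture-storage expansion). The curve is scaled so
#' the April-September (day-of-year 91-273) mean equals `season_mean_um`.
#'
#' @param peak_doy day of year of maximum growth rate (default 135, mid-May).
#' @param sigma_left,sigma_right spread (days) of the rise and decay limbs.
#' @param base_um_day year-round base rate (um/day) before soil-temperature
#'   gating.
#' @param season_mean_um target mean daily increment (um) over day-of-year
#'   91-273.
#' @return numeric vector of length 366 (um/day by day of year).
#' @export
default_growth_curve <- function(peak_doy = 135, sigma_left = 30,
                                 sigma_right = 75, base_um_day = 0.5,
                                 season_mean_um = 15) {
  doy <- seq_len(366)
  z <- ifelse(doy < peak_doy, (doy - peak_doy) / sigma_left,
              (doy - peak_doy) / sigma_right)
  g <- exp(-0.5 * z^2)
  season <- 91:273
  scale <- (season_mean_um - base_um_day) / mean(g[season])
  pmax(0, base_um_day + scale * g)
}

#' Stem generator configuration
#'
#' @param n_trees number of simulated trees.
#' @param baseline_radius sensor-relative starting displacement (um).
#' @param diel_amplitude diel contraction depth (um): daily fall from the
#'   pre-noon maximum to the evening minimum. May be 0 (no diel cycle).
#' @param growth_curve daily true-increment rate by day of year (um/day,
#'   length 366); defaults to [default_growth_curve()].
#' @param sri_noise_sd half-hourly reading noise sd (um).
#' @param soil_temp_onset_threshold growth is gated to zero on days whose mean
#'   soil temperature is below this value (C).
#' @param climate_sensitivity list with `spring_tsoil` and `monsoon_precip`:
#'   log-linear strengths of the built-in dependence of daily increment on the
#'   soil-temperature anomaly (April-May) and on the precipitation anomaly
#'   (June-July). Set to 0 to disable.
#' @param tree_spread_sd log-sd of the per-tree growth multiplier.
#' @param artifact_rates list for [inject_artifacts()]: `gap_prob` and
#'   `spike_prob` (per-slot probabilities), `spike_gamma_shape` and
#'   `spike_gamma_scale` (um; the implied spike distribution has substantial
#'   mass above the 350 um spurious threshold), `outage_rate_per_year` and
#'   `outage_mean_days` (full-day power-outage windows).
#' @param seed integer root seed; per-tree substreams are drawn from it.
#' @return object of class `stem_config`.
#' @export
stem_config <- function(n_trees = 5,
                        baseline_radius = 5000,
                        diel_amplitude = 60,
                        growth_curve = NULL,
                        sri_noise_sd = 2,
                        soil_temp_onset_threshold = 5,
                        climate_sensitivity = list(spring_tsoil = 0.5,
                                                   monsoon_precip = 0.5),
                        tree_spread_sd = 0.05,
                        artifact_rates = list(gap_prob = 0.002,
                                              spike_prob = 0.0003,
                                              spike_gamma_shape = 1.5,
                                              spike_gamma_scale = 300,
                                              outage_rate_per_year = 3,
                                              outage_mean_days = 4),
                        seed = 1L) {
  if (is.null(growth_curve)) growth_curve <- default_growth_curve()
  cfg <- list(n_trees = n_trees, baseline_radius = baseline_radius,
              diel_amplitude = diel_amplitude, growth_curve = growth_curve,
              sri_noise_sd = sri_noise_sd,
              soil_temp_onset_threshold = soil_temp_onset_threshold,
              climate_sensitivity = climate_sensitivity,
              tree_spread_sd = tree_spread_sd,
              artifact_rates = artifact_rates, seed = seed)
  validate_stem_config(cfg)
  class(cfg) <- "stem_config"
  cfg
}

validate_stem_config <- function(cfg) {
  if (cfg$n_trees < 1) stop_invalid("n_trees", "must be >= 1")
  if (cfg$diel_amplitude < 0) stop_invalid("diel_amplitude", "must be >= 0")
  if (length(cfg$growth_curve) != 366 || any(cfg$growth_curve < 0)) {
    stop_invalid("growth_curve", "must be 366 non-negative daily rates")
  }
  if (cfg$sri_noise_sd < 0) stop_invalid("sri_noise_sd", "must be >= 0")
  ar <- cfg$artifact_rates
  for (f in c("gap_prob", "spike_prob")) {
    if (ar[[f]] < 0 || ar[[f]] > 1) stop_invalid(f, "must be a probability in [0, 1]")
  }
  if (ar$outage_rate_per_year < 0) stop_invalid("outage_rate_per_year", "must be >= 0")
  invisible(cfg)
}

# diel shape: double cosine ramp, minimum at 18:30, maximum at 11:30, in [-1, 1]
diel_shape <- function(h) {
  u <- (h - 18.5) %% 24
  ifelse(u <= 17, -cos(pi * u / 17), cos(pi * (u - 17) / 7))
}

#' Generate synthetic stem-radius series
#'
#' Builds one half-hourly stem-size series per tree over the span of `weather`:
#' baseline + cumulative true increment + diel cycle (pre-noon maximum from
#' nocturnal recharge, afternoon/evening contraction) + reading noise. The true
#' daily increment follows the seasonal growth curve, is gated to zero on days
#' with mean soil temperature below the onset threshold, and carries a built-in
#' positive dependence on the soil-temperature anomaly in April-May and on the
#' precipitation anomaly in June-July (the signals the response analysis is
#' expected to recover). The exact daily increments are returned as ground
#' truth on a separate channel that the processing pipeline never reads.
#'
#' @param stem_cfg a [stem_config()].
#' @param weather half-hourly weather frame from [generate_weather()] (or the
#'   ingest module); must cover whole days without internal gaps.
#' @param site_id site label attached to all series.
#' @param seed overrides `stem_cfg$seed` when given.
#' @return list with `series` (long data.frame: `timestamp`, `site_id`,
#'   `tree_id`, `stem_um`, `flag`) and `truth` (data.frame: `date`, `tree_id`,
#'   `true_increment_um`).
#' @export
generate_stem_series <- function(stem_cfg = stem_config(), weather,
                                 site_id = "S1", seed = stem_cfg$seed) {
  n <- nrow(weather)
  if (n < SLOTS_PER_DAY) stop("weather span shorter than one full day")
  if (n %% SLOTS_PER_DAY != 0) stop("weather must cover whole calendar days")
  if (any(diff(as.numeric(weather$timestamp)) != SLOT_SECONDS)) {
    stop("weather timestamps must form a continuous half-hour grid")
  }
  with_seed(seed, {
    dates <- grid_date(weather$timestamp[seq(1, n, by = SLOTS_PER_DAY)])
    n_days <- length(dates)
    doy <- as.POSIXlt(dates)$yday + 1
    mon <- as.POSIXlt(dates)$mon + 1
    day_of <- rep(seq_len(n_days), each = SLOTS_PER_DAY)

    tsoil_day <- rowsum(weather$tsoil, day_of)[, 1] / SLOTS_PER_DAY
    prec_day <- rowsum(weather$precip, day_of)[, 1]
    gate <- as.numeric(tsoil_day >= stem_cfg$soil_temp_onset_threshold)

    # month-standardized anomalies driving the encoded climate signals
    z_by_month <- function(x) {
      out <- numeric(length(x))
      for (m in unique(mon)) {
        i <- mon == m
        s <- stats::sd(x[i])
        out[i] <- if (is.na(s) || s < 1e-8) 0 else (x[i] - mean(x[i])) / s
      }
      out
    }
    zT <- z_by_month(tsoil_day)
    zP <- z_by_month(log1p(prec_day))
    bT <- stem_cfg$climate_sensitivity$spring_tsoil
    bP <- stem_cfg$climate_sensitivity$monsoon_precip
    mod <- rep(1, n_days)
    spring <- mon %in% c(4, 5)
    monsoon <- mon %in% c(6, 7)
    mod[spring] <- exp(bT * zT[spring])
    mod[monsoon] <- exp(bP * zP[monsoon])
    mod <- pmin(3.5, pmax(0.15, mod))
    # normalize to mean one within each year-month: the climate signal
    # redistributes growth within a month without changing its total
    ymk <- paste(format(dates, "%Y"), mon)
    mod <- mod / stats::ave(mod, ymk)

    g_day <- stem_cfg$growth_curve[doy] * gate * mod

    h48 <- seq(0, 23.5, by = 0.5)
    r_slot <- rep(pmin(1, h48 / 11.5), n_days)   # growth complete by 11:30
    w_slot <- rep(diel_shape(h48), n_days)
    half_amp <- stem_cfg$diel_amplitude / 2

    tree_seeds <- sample.int(.Machine$integer.max, stem_cfg$n_trees)
    series <- vector("list", stem_cfg$n_trees)
    truth <- vector("list", stem_cfg$n_trees)
    for (k in seq_len(stem_cfg$n_trees)) {
      with_seed(tree_seeds[k], {
        tf <- exp(stats::rnorm(1, 0, stem_cfg$tree_spread_sd) -
                    stem_cfg$tree_spread_sd^2 / 2)
        inc <- g_day * tf
        c_prev <- c(0, cumsum(inc)[-n_days])
        stem <- stem_cfg$baseline_radius + rep(c_prev, each = SLOTS_PER_DAY) +
          rep(inc, each = SLOTS_PER_DAY) * r_slot + half_amp * w_slot +
          stats::rnorm(n, 0, stem_cfg$sri_noise_sd)
        tid <- sprintf("T%02d", k)
        series[[k]] <- data.frame(timestamp = weather$timestamp,
                                  site_id = site_id, tree_id = tid,
                                  stem_um = stem, flag = "ok")
        truth[[k]] <- data.frame(date = dates, tree_id = tid,
                                 true_increment_um = inc)
      })
    }
    structure(list(series = do.call(rbind, series),
                   truth = do.call(rbind, truth)),
              class = "stem_sim")
  })
}

#' Inject sensor artifacts into a stem series
#'
#' Adds the failure modes seen in field deployments: isolated missing readings,
#' multi-day power-outage windows (full calendar days lost), and additive
#' positive spikes (some exceeding the 350 um spurious-SRI threshold). Every
#' injected artifact is logged with type, tree and position so that downstream
#' filters can be scored against it. Deterministic under a fixed seed.
#'
#' @param series long stem-series data.frame (as in the `series` element of
#'   [generate_stem_series()]).
#' @param stem_cfg a [stem_config()]; its `artifact_rates` are used.
#' @param seed overrides `stem_cfg$seed` when given.
#' @return list with `series` (modified frame; corrupted slots flagged
#'   `"missing"` with `NA` values) and `log` (data.frame: `type`, `tree_id`,
#'   `timestamp`, `n_slots`, `magnitude_um`).
#' @export
inject_artifacts <- function(series, stem_cfg, seed = stem_cfg$seed) {
  validate_stem_config(stem_cfg)
  ar <- stem_cfg$artifact_rates
  with_seed(seed, {
    out <- series
    logs <- list()
    for (tid in unique(series$tree_id)) {
      idx <- which(series$tree_id == tid)
      ts <- series$timestamp[idx]
      n <- length(idx)
      d <- grid_date(ts)
      days <- unique(d)
      n_years <- length(days) / 365.25

      n_out <- stats::rpois(1, ar$outage_rate_per_year * n_years)
      if (n_out > 0) {
        for (j in seq_len(n_out)) {
          start_day <- sample(seq_along(days), 1)
          dur <- 1 + stats::rgeom(1, 1 / ar$outage_mean_days)
          hit <- d %in% days[start_day:min(length(days), start_day + dur - 1)]
          out$stem_um[idx[hit]] <- NA_real_
          out$flag[idx[hit]] <- "missing"
          logs[[length(logs) + 1]] <- data.frame(
            type = "outage", tree_id = tid, timestamp = ts[which(hit)[1]],
            n_slots = sum(hit), magnitude_um = NA_real_)
        }
      }

      gap <- stats::runif(n) < ar$gap_prob
      if (any(gap)) {
        out$stem_um[idx[gap]] <- NA_real_
        out$flag[idx[gap]] <- "missing"
        logs[[length(logs) + 1]] <- data.frame(
          type = "gap", tree_id = tid, timestamp = ts[gap],
          n_slots = 1L, magnitude_um = NA_real_)
      }

      spike <- stats::runif(n) < ar$spike_prob & out$flag[idx] == "ok"
      if (any(spike)) {
        mag <- stats::rgamma(sum(spike), shape = ar$spike_gamma_shape,
                             scale = ar$spike_gamma_scale)
        out$stem_um[idx[spike]] <- out$stem_um[idx[spike]] + mag
        logs[[length(logs) + 1]] <- data.frame(
          type = "spike", tree_id = tid, timestamp = ts[spike],
          n_slots = 1L, magnitude_um = mag)
      }
    }
    log <- if (length(logs)) do.call(rbind, logs) else
      data.frame(type = character(), tree_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 n_slots = integer(), magnitude_um = numeric())
    list(series = out, log = log)
  })
}

#' Superimpose a beetle-infestation stem decline
#'
#' Models the progressive stem-size decrease documented on infested trees: a
#' linear shrinkage at `rate` um/day starting at `onset_day`, superimposed on
#' the recorded readings. Because SRI floors negative day-over-day differences
#' at zero, the cumulative SRI of a declining tree plateaus rather than
#' decreasing.
#'
#' @param series long stem-series data.frame.
#' @param onset_day Date at which decline begins (must lie within the span).
#' @param rate decline rate (um/day, >= 0; 0 is the identity).
#' @return modified series data.frame.
#' @export
beetle_decline_scenario <- function(series, onset_day, rate) {
  onset_day <- as.Date(onset_day)
  if (rate < 0) stop("rate must be >= 0")
  d <- grid_date(series$timestamp)
  if (onset_day < min(d) || onset_day > max(d)) {
    stop("onset_day lies outside the series span")
  }
  el <- as.numeric(difftime(series$timestamp,
                            as.POSIXct(paste(onset_day, "00:00:00"), tz = "UTC"),
                            units = "days"))
  series$stem_um <- series$stem_um - rate * pmax(0, el)
  series
}
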