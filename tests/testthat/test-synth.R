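# Synthetic weather and stem generator behaviour.

test_that("invalid climate configurations are rejected by name", {
  expect_error(climate_config(monthly_precip_mm = c(rep(10, 11), -1)),
               "monthly_precip_mm")
  expect_error(climate_config(monthly_rh_mean = c(rep(50, 11), 105)),
               "monthly_rh_mean")
  expect_error(climate_config(soil_smooth_alpha = 1.2), "soil_smooth_alpha")
})

test_that("weather generation is deterministic and grid-complete", {
  w1 <- generate_weather(climate_config(), years = 1, seed = 3)
  w2 <- generate_weather(climate_config(), years = 1, seed = 3)
  expect_identical(w1, w2)
  w3 <- generate_weather(climate_config(), years = 1, seed = 4)
  expect_false(identical(w1$precip, w3$precip))
  expect_equal(nrow(w1), 365 * 48)
  expect_true(all(diff(as.numeric(w1$timestamp)) == 1800))
  expect_true(all(w1$precip >= 0))
  expect_true(all(w1$rh >= 0 & w1$rh <= 100))
  expect_true(all(w1$solrad >= 0))
})

test_that("zero-precipitation config yields zero precipitation everywhere", {
  cfg <- climate_config(monthly_precip_mm = rep(0, 12))
  w <- generate_weather(cfg, years = 1, seed = 5)
  expect_true(all(w$precip == 0))
})

test_that("air temperature and radiation carry diel cycles; soil is damped", {
  w <- generate_weather(climate_config(), years = 1, seed = 6)
  h <- grid_hour(w$timestamp)
  afternoon <- h >= 12 & h < 16
  night <- h >= 0 & h < 4
  expect_gt(mean(w$tair[afternoon]), mean(w$tair[night]) + 5)
  expect_equal(mean(w$solrad[night]), 0)
  expect_gt(mean(w$solrad[afternoon]), 0)
  # soil diurnal range much smaller than air diurnal range
  d <- grid_date(w$timestamp)
  rng <- function(x) tapply(x, d, max) - tapply(x, d, min)
  expect_lt(mean(rng(w$tsoil)), 0.5 * mean(rng(w$tair)))
  # RH anti-phased with the afternoon temperature peak
  expect_lt(mean(w$rh[afternoon]), mean(w$rh[night]))
})

test_that("half-hourly precipitation aggregates without leakage", {
  w <- generate_weather(climate_config(), years = 1, seed = 8)
  d <- daily_weather(w)
  expect_equal(sum(d$prec_total), sum(w$precip))
})

test_that("stem series construction matches its ground truth exactly when clean", {
  w <- generate_weather(climate_config(), years = 1, seed = 11)
  sim <- generate_stem_series(small_stem_cfg(), w, seed = 2)
  s <- sri(daily_max(sim$series))
  for (tid in unique(s$tree_id)) {
    m <- merge(s[s$tree_id == tid, ], sim$truth[sim$truth$tree_id == tid, ])
    expect_equal(m$sri[-1], m$true_increment_um[-1], tolerance = 1e-8)
  }
})

test_that("flat growth with no diel cycle and no noise gives constant SRI", {
  w <- generate_weather(climate_config(), years = 1, seed = 12)
  cfg <- small_stem_cfg(growth_curve = rep(10, 366),
                        soil_temp_onset_threshold = -100)
  sim <- generate_stem_series(cfg, w, seed = 1)
  s <- sri(daily_max(sim$series))
  expect_true(all(abs(s$sri[-c(1, 366)] - 10) < 1e-8, na.rm = TRUE))
})

test_that("growth is gated off when soil temperature never crosses the onset", {
  w <- generate_weather(climate_config(), years = 1, seed = 13)
  w$tsoil <- 0
  sim <- generate_stem_series(stem_config(n_trees = 2), w, seed = 1)
  expect_equal(sum(sim$truth$true_increment_um), 0)
})

test_that("daily maximum falls before 14:00 on the vast majority of days", {
  w <- generate_weather(climate_config(), years = 1, seed = 14)
  sim <- generate_stem_series(stem_config(n_trees = 1), w, seed = 3)
  one <- sim$series
  h <- grid_hour(one$timestamp)
  d <- grid_date(one$timestamp)
  peak_h <- tapply(seq_along(h), d, function(i) h[i][which.max(one$stem_um[i])])
  expect_gt(mean(peak_h < 14), 0.8)
})

test_that("stem generation requires at least one full day of weather", {
  w <- generate_weather(climate_config(), years = 1, seed = 15)
  expect_error(generate_stem_series(stem_config(), w[1:20, ]),
               "shorter than one full day")
})

test_that("artifact injection is an identity at zero rates and logs otherwise", {
  w <- generate_weather(climate_config(), years = 1, seed = 16)
  sim <- generate_stem_series(stem_config(n_trees = 2), w, seed = 4)
  cfg0 <- stem_config(n_trees = 2,
                      artifact_rates = list(gap_prob = 0, spike_prob = 0,
                                            spike_gamma_shape = 1.5,
                                            spike_gamma_scale = 200,
                                            outage_rate_per_year = 0,
                                            outage_mean_days = 4))
  out0 <- inject_artifacts(sim$series, cfg0, seed = 5)
  expect_identical(out0$series, sim$series)
  expect_equal(nrow(out0$log), 0)

  cfg1 <- stem_config(n_trees = 2)
  out1 <- inject_artifacts(sim$series, cfg1, seed = 5)
  expect_gt(nrow(out1$log), 0)
  expect_setequal(intersect(unique(out1$log$type), c("gap", "spike", "outage")),
                  unique(out1$log$type))
  expect_true(any(out1$series$flag == "missing"))
  # deterministic under the same seed
  out2 <- inject_artifacts(sim$series, cfg1, seed = 5)
  expect_identical(out1, out2)
  expect_error(inject_artifacts(sim$series,
                                stem_config(artifact_rates = list(
                                  gap_prob = 2, spike_prob = 0,
                                  spike_gamma_shape = 1, spike_gamma_scale = 1,
                                  outage_rate_per_year = 0,
                                  outage_mean_days = 1))),
               "gap_prob")
})

test_that("a spike above the spurious threshold knocks out that day's SRI", {
  w <- generate_weather(climate_config(), years = 1, seed = 17)
  sim <- generate_stem_series(small_stem_cfg(n_trees = 1), w, seed = 6)
  s0 <- sri(daily_max(sim$series))
  target <- as.Date("2002-06-15")
  i <- which(grid_date(sim$series$timestamp) == target)
  j <- i[which.max(sim$series$stem_um[i])]
  spiked <- sim$series
  spiked$stem_um[j] <- spiked$stem_um[j] + 400
  s1 <- sri(daily_max(spiked))
  expect_false(is.na(s0$sri[s0$date == target]))
  expect_true(is.na(s1$sri[s1$date == target]))
  expect_equal(s1$basis[s1$date == target], "spurious")
})

test_that("a full-day outage removes the day and its successor's comparison", {
  w <- generate_weather(climate_config(), years = 1, seed = 18)
  sim <- generate_stem_series(small_stem_cfg(n_trees = 1), w, seed = 7)
  target <- as.Date("2002-07-10")
  out <- sim$series
  hit <- grid_date(out$timestamp) == target
  out$stem_um[hit] <- NA
  out$flag[hit] <- "missing"
  dm <- daily_max(out)
  expect_true(is.na(dm$day_max[dm$date == target]))
  s <- sri(dm)
  expect_true(is.na(s$sri[s$date == target]))
  expect_true(is.na(s$sri[s$date == target + 1]))
  expect_equal(s$basis[s$date == target + 1], "no_previous_max")
})

test_that("beetle decline floors SRI at zero and never raises cumulative growth", {
  w <- generate_weather(climate_config(), years = 1, seed = 19)
  # flat no-growth tree: any decline must give SRI = 0 after onset
  flat <- small_stem_cfg(n_trees = 1, growth_curve = rep(0, 366))
  simf <- generate_stem_series(flat, w, seed = 8)
  onset <- as.Date("2002-06-01")
  dec <- beetle_decline_scenario(simf$series, onset, rate = 5)
  s <- sri(daily_max(dec))
  after <- s$date > onset
  expect_true(all(s$sri[after] == 0, na.rm = TRUE))
  # identity at rate zero
  expect_equal(beetle_decline_scenario(simf$series, onset, 0), simf$series)
  expect_error(beetle_decline_scenario(simf$series, as.Date("1990-01-01"), 1),
               "outside the series span")

  # growing tree: cumulative SRI can only be reduced by the decline
  simg <- generate_stem_series(stem_config(n_trees = 1), w, seed = 9)
  s0 <- cumulative_sri(sri(daily_max(simg$series)))
  s1 <- cumulative_sri(sri(daily_max(
    beetle_decline_scenario(simg$series, onset, rate = 8))))
  expect_true(all(s1$cum_sri <= s0$cum_sri + 1e-8))
})
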