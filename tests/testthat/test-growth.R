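# SRI rules, derived growth quantities and thermal-error arithmetic.

test_that("the SRI rules reproduce the canonical toy sequence", {
  s <- sri(dm_frame(c(1000, 1015, 1010, 1400)))
  expect_equal(s$sri, c(NA, 15, 0, NA))
  expect_equal(s$basis, c("no_previous_max", "ok", "ok", "spurious"))
})

test_that("SRI boundary and gap conventions hold", {
  # a difference of exactly 350 um is retained (strict > threshold)
  s <- sri(dm_frame(c(1000, 1350)))
  expect_equal(s$sri[2], 350)
  # constant maxima give zero SRI after the first day
  s2 <- sri(dm_frame(rep(500, 5)))
  expect_equal(s2$sri, c(NA, 0, 0, 0, 0))
  # a gap in the calendar is never compared across
  dm <- dm_frame(c(1000, 1010, 1030))
  dm$date[3] <- dm$date[3] + 2  # skip two days
  s3 <- sri(dm)
  expect_equal(nrow(s3), 5)
  expect_equal(s3$basis[4:5], c("no_previous_max", "no_previous_max"))
  # arbitrarily large drops floor to zero, they are not spurious
  s4 <- sri(dm_frame(c(2000, 1000)))
  expect_equal(s4$sri[2], 0)
})

test_that("sri matches a brute-force oracle on random 30-day series", {
  set.seed(77)
  for (rep in 1:20) {
    dm <- 1000 + cumsum(rnorm(30, 5, 60))
    dm[sample.int(30, 3)] <- NA
    dm[sample.int(30, 1)] <- dm[sample.int(30, 1)] + 500  # force some spurious
    s <- sri(dm_frame(dm))
    expect_equal(s$sri, sri_oracle(dm))
  }
})

test_that("SRI is invariant to the sensor origin", {
  set.seed(5)
  dm <- 1000 + cumsum(rnorm(30, 5, 40))
  expect_equal(sri(dm_frame(dm))$sri, sri(dm_frame(dm + 12345))$sri)
})

test_that("daily_max respects flags and missing days", {
  ts <- half_hour_grid("2002-03-01", 2)
  x <- data.frame(timestamp = ts, site_id = "S1", tree_id = "T01",
                  stem_um = c(rep(1000, 48), rep(NA, 48)),
                  flag = c(rep("ok", 48), rep("missing", 48)))
  x$stem_um[10] <- 1234
  dm <- daily_max(x)
  expect_equal(dm$day_max, c(1234, NA))
  # a single reading is enough for a maximum
  y <- x[1:48, ]
  y$stem_um <- NA; y$stem_um[5] <- 1000
  expect_equal(daily_max(y)$day_max, 1000)
})

test_that("cumulative SRI skips missing days but counts them", {
  cum <- cumulative_sri(data.frame(
    date = seq(as.Date("2002-01-01"), by = "day", length.out = 4),
    sri = c(5, 0, NA, 10)))
  expect_equal(cum$cum_sri, c(5, 5, 5, 15))
  expect_equal(attr(cum, "n_missing"), 1)
  expect_true(all(diff(cum$cum_sri) >= 0))
  allna <- cumulative_sri(data.frame(
    date = seq(as.Date("2002-01-01"), by = "day", length.out = 3),
    sri = rep(NA_real_, 3)))
  expect_equal(allna$cum_sri, c(0, 0, 0))
  expect_equal(attr(allna, "n_missing"), 3)
})

test_that("monthly growth fractions behave and conserve the annual total", {
  dates <- seq(as.Date("2002-01-01"), as.Date("2002-12-31"), by = "day")
  mon <- as.POSIXlt(dates)$mon + 1
  # all growth in May
  x <- data.frame(date = dates, sri = ifelse(mon == 5, 2, 0))
  f <- monthly_growth_fraction(x, 2002)
  expect_equal(f$fraction[5], 100)
  expect_equal(sum(f$fraction), 100)
  # uniform growth: shares proportional to month lengths
  u <- data.frame(date = dates, sri = 1)
  fu <- monthly_growth_fraction(u, 2002)
  expect_equal(fu$fraction, 100 * as.numeric(table(mon)) / 365)
  # zero total flagged
  z <- data.frame(date = dates, sri = 0)
  expect_warning(fz <- monthly_growth_fraction(z, 2002), "undefined")
  expect_true(all(is.na(fz$fraction)))
})

test_that("growing season selects the longest strict run with earliest tie-break", {
  f <- c(1, 2, 3, 10, 20, 15, 12, 8, 6, 3, 1, 1)  # Apr-Sep above 5
  expect_equal(growing_season(f), 4:9)
  expect_equal(growing_season(rep(100 / 12, 12)), 1:12)  # 8.33% everywhere
  expect_equal(growing_season(c(9, 9, 0, 0, 9, 9, 0, 0, 0, 0, 0, 0)), 1:2)
  expect_equal(growing_season(rep(1, 12)), integer(0))
})

test_that("onset day requires a sustained soil-temperature crossing", {
  dates <- seq(as.Date("2002-01-01"), by = "day", length.out = 200)
  warm <- data.frame(date = dates, tsoil = 10)
  expect_equal(onset_day(warm), dates[1])
  cold <- data.frame(date = dates, tsoil = 0)
  expect_message(o <- onset_day(cold), "no onset")
  expect_true(is.na(o))
  step <- data.frame(date = dates, tsoil = ifelse(seq_along(dates) >= 100, 8, 2))
  expect_equal(onset_day(step), dates[100])
  # a 3-day blip does not trigger onset with the default 5-day run
  blip <- data.frame(date = dates, tsoil = c(rep(2, 50), rep(8, 3), rep(2, 147)))
  expect_message(ob <- onset_day(blip), "no onset")
  expect_true(is.na(ob))
})

test_that("diel phases decompose canonical day shapes", {
  # monotone rising day: no contraction, increment = net rise
  rise <- seq(1000, 1094, by = 2)
  p <- diel_phases(rise, prev_max = 1000)
  expect_equal(p$contraction, 0)
  expect_equal(p$increment, 94)
  # V-shape returning to its start: expansion equals contraction, increment 0
  v <- c(seq(1100, 1004, by = -4), seq(1008, 1100, by = 4))
  pv <- diel_phases(v, prev_max = 1100)
  expect_equal(pv$increment, 0)
  expect_equal(pv$expansion, pv$contraction)
  # insufficient coverage
  short <- c(rise[1:20], rep(NA, 28))
  expect_true(is.na(diel_phases(short, 1000)$contraction))
  # noise-free synthetic day recovers the generator's increment
  w <- generate_weather(climate_config(), years = 1, seed = 33)
  sim <- generate_stem_series(small_stem_cfg(n_trees = 1, diel_amplitude = 40),
                              w, seed = 2)
  d <- as.Date("2002-05-20")
  day <- sim$series$stem_um[grid_date(sim$series$timestamp) == d]
  prev <- max(sim$series$stem_um[grid_date(sim$series$timestamp) == d - 1])
  ph <- diel_phases(day, prev)
  truth <- sim$truth$true_increment_um[sim$truth$date == d]
  expect_equal(ph$increment, truth, tolerance = 1e-8)
})

test_that("site-level SRI equals single-tree SRI for identical clean trees", {
  w <- generate_weather(climate_config(), years = 1, seed = 34)
  sim <- generate_stem_series(small_stem_cfg(n_trees = 3), w, seed = 3)
  s <- sri(daily_max(sim$series))
  agg <- site_sri(s)
  one <- s[s$tree_id == "T01", ]
  expect_equal(agg$sri, one$sri)
  med <- site_sri(s, method = "median")
  expect_equal(med$sri, one$sri)
})

test_that("thermal-expansion error arithmetic matches the published coefficients", {
  expect_equal(thermal_error(thermal_spec("point"), 10), 17)
  expect_equal(thermal_error(thermal_spec("band"), 10), 112)
  expect_equal(thermal_error(thermal_spec("band"), 0), 0)
  expect_equal(thermal_error(thermal_spec("point"), -10), -17)
  tr <- thermal_spec("point", trunk_cte = -3)
  expect_equal(thermal_error(tr, 10, include_trunk = TRUE), (17 - 3) * 0.1 * 10)
  expect_error(thermal_spec("point", cte = -1), "cte")
})
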