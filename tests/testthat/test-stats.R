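# Bootstrap correlation, PCR and the response table.

test_that("month eligibility is inclusive at 21 paired days", {
  mk <- function(n, start) {
    dates <- seq(as.Date(start), by = "day", length.out = n)
    cbind(data.frame(date = dates, sri = rnorm(n)),
          as.data.frame(matrix(rnorm(n * 12), n,
                               dimnames = list(NULL, response_variables()))))
  }
  set.seed(1)
  panels <- list("2002-04" = mk(25, "2002-04-01"),
                 "2002-05" = mk(20, "2002-05-01"),
                 "2002-06" = mk(21, "2002-06-01"))
  keep <- eligible_months(panels)
  expect_setequal(names(keep), c("2002-04", "2002-06"))
  expect_equal(unname(attr(keep[["2002-04"]], "n_days")["Prec"]), 25L)
})

test_that("a perfect linear relationship is significant with median near one", {
  set.seed(2)
  x <- rnorm(30)
  b <- boot_correlation(x, 2 * x, n_boot = 500, seed = 9)
  expect_true(b$significant)
  expect_equal(b$median_coef, 1)
  expect_true(b$q2_5 <= b$median_coef & b$median_coef <= b$q97_5)
})

test_that("bootstrap correlations match an independent per-resample oracle", {
  # tiny printed toy panel; shared resample-index stream
  x <- c(1.2, -0.7, 0.3, 2.1, -1.5)
  y <- c(0.9, -0.2, 0.1, 1.7, -1.1)
  n_boot <- 25
  b <- boot_correlation(x, y, n_boot = n_boot, seed = 123, min_n = 5)
  set.seed(123)
  idx <- matrix(sample.int(5, 5 * n_boot, replace = TRUE), nrow = 5)
  r_oracle <- apply(idx, 2, function(i) stats::cor(x[i], y[i]))
  expect_equal(b$median_coef,
               unname(stats::quantile(r_oracle, 0.5, type = 7)))
  expect_equal(b$q97_5, unname(stats::quantile(r_oracle, 0.975, type = 7)))
  # determinism under the seed
  b2 <- boot_correlation(x, y, n_boot = n_boot, seed = 123, min_n = 5)
  expect_identical(b, b2)
})

test_that("degenerate inputs are rejected by name", {
  expect_error(boot_correlation(rep(1, 30), rnorm(30)), "zero variance in x")
  expect_error(boot_correlation(rnorm(30), rep(2, 30)), "zero variance in y")
  expect_error(boot_correlation(rnorm(10), rnorm(10)), "insufficient")
})

test_that("retaining all components reproduces ordinary least squares", {
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(n, 0, 0.5)
  fit <- pc_regression(X, y, eigen_frac = 0)
  ols <- stats::lm(y ~ X)
  expect_equal(unname(fit$coef), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit$components_retained, 5)
})

test_that("duplicated predictors split their loading equally", {
  set.seed(4)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(a = x1, b = x1, c = x2)
  y <- 3 * x1 + x2 + rnorm(n, 0, 0.2)
  fit <- pc_regression(X, y)  # zero eigenvalue dropped by the selection rule
  expect_equal(fit$coef[["a"]], fit$coef[["b"]], tolerance = 1e-8)
  expect_lt(fit$components_retained, 3)
})

test_that("a single predictor reduces to the simple-regression slope", {
  set.seed(5)
  x <- rnorm(35); y <- 1.5 * x + rnorm(35)
  fit <- pc_regression(matrix(x, dimnames = list(NULL, "x")), y,
                       eigen_frac = 0)
  expect_equal(unname(fit$coef),
               stats::cor(x, y) * stats::sd(y) / stats::sd(x),
               tolerance = 1e-8)
})

test_that("bootstrapped PCR flags a strong single signal with the right sign", {
  set.seed(6)
  n <- 31
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, names(response_variables())))
  y <- 2 * X[, 1] + rnorm(n, 0, 0.7)
  bp <- boot_pcr(X, y, n_boot = 300, seed = 10)
  expect_true(bp[[1]]$significant)
  expect_gt(bp[[1]]$median_coef, 0)
  expect_equal(sign(bp[[1]]$median_coef), sign(stats::cor(X[, 1], y)))
  bp2 <- boot_pcr(X, y, n_boot = 300, seed = 10)
  expect_identical(bp, bp2)
})

test_that("pure-noise designs are mostly non-significant under bootstrapped PCR", {
  set.seed(7)
  n <- 31
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, names(response_variables())))
  y <- rnorm(n)
  bp <- boot_pcr(X, y, n_boot = 300, seed = 11)
  expect_lte(sum(vapply(bp, `[[`, logical(1), "significant")), 4)
})

test_that("the response table formats coefficients, ns and availability markers", {
  res <- data.frame(
    month = c("2002-07", "2002-07", "2002-07"),
    variable = c("RH", "AirPr", "SolRad"),
    method = "correlation",
    median_coef = c(0.54, -0.42, NA),
    q2_5 = NA, q97_5 = NA, half_width = NA,
    significant = c(TRUE, TRUE, NA),
    n_days = c(28L, 28L, 0L), n_boot = 25L, seed = 1L)
  res <- rbind(res, within(res[1, ], {
    variable <- "Prec"; median_coef <- 0.1; significant <- FALSE
  }))
  tab <- response_table(res)
  expect_equal(tab["2002-07", "RH"], "0.54")
  expect_equal(tab["2002-07", "AirPr"], "-0.42")
  expect_equal(tab["2002-07", "SolRad"], "/")
  expect_equal(tab["2002-07", "Prec"], "ns")
  expect_equal(tab["2002-07", "VPD"], "/")  # never tested -> unavailable
  expect_equal(colnames(tab), names(response_variables()))
})

test_that("monthly response runs end to end on simulated data deterministically", {
  wx <- generate_weather(climate_config(), years = 1, seed = 40)
  sim <- generate_stem_series(stem_config(n_trees = 3), wx, seed = 41)
  d <- daily_weather(wx)
  ss <- site_sri(sri(daily_max(sim$series)))
  panels <- month_panels(ss, d)
  expect_true(length(panels) >= 12)
  res <- boot_climate_response(panels[c("2002-04", "2002-05")],
                               n_boot = 200, seed = 50)
  expect_equal(nrow(res), 24)
  res2 <- boot_climate_response(panels[c("2002-04", "2002-05")],
                                n_boot = 200, seed = 50)
  expect_identical(res, res2)
  # the encoded spring soil-temperature signal shows up positive
  r_ts <- res[res$variable %in% c("TSmax", "TSmin"), ]
  expect_true(all(r_ts$median_coef > 0))
})
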