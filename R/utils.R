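# Shared helpers: the half-hour grid, safe aggregation, seasonal interpolation.

SLOTS_PER_DAY <- 48L
SLOT_SECONDS <- 1800L

#' Half-hour timestamp grid
#'
#' Builds the continuous half-hourly grid (naive local standard time, stored as
#' UTC POSIXct) spanning `n_days` calendar days from local midnight of
#' `start_date`. Slot timestamps run 00:00, 00:30, ..., 23:30; each stamp
#' labels the half-hour interval it closes, so accumulation channels
#' (precipitation, solar radiation) hold the interval's total.
#'
#' @param start_date Date (or coercible) of the first day.
#' @param n_days number of calendar days to span.
#' @return POSIXct vector of length `48 * n_days`.
#' @export
half_hour_grid <- function(start_date, n_days) {
  start_date <- as.Date(start_date)
  stopifnot(n_days >= 1)
  out <- seq(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
             by = SLOT_SECONDS, length.out = as.integer(n_days) * SLOTS_PER_DAY)
  # store as double so generated and re-read grids are bit-identical
  structure(as.double(out), class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

# max/min/mean/sum that return NA (not -Inf/warnings) when all values missing
max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)

grid_date <- function(ts) as.Date(ts, tz = "UTC")
grid_hour <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60
}

#' Interpolate monthly climatology to a smooth day-of-year curve
#'
#' Periodic spline through the twelve monthly values placed at month
#' mid-points, evaluated at arbitrary days of year. Used to turn monthly
#' climate normals into continuous seasonal baselines.
#'
#' @param monthly numeric vector of 12 monthly values (Jan..Dec).
#' @param doy day-of-year vector (1..366).
#' @return numeric vector of interpolated values, same length as `doy`.
#' @export
monthly_to_doy <- function(monthly, doy) {
  stopifnot(length(monthly) == 12)
  mid <- c(15, 46, 75, 105, 136, 166, 197, 228, 258, 289, 319, 350)
  x <- c(mid - 365, mid, mid + 365)
  y <- rep(monthly, 3)
  stats::spline(x, y, xout = doy, method = "fmm")$y
}

# AR(1) series with marginal sd `sd` and lag-1 correlation `rho`
ar1 <- function(n, rho, sd) {
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# run RNG-dependent code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
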