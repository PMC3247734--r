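# Stem Radial Increment (SRI) and derived growth quantities.
#
# SRI for a day is the current day's maximum stem size minus the previous
# day's maximum: negative differences are set to zero (shrinkage is reversible
# water loss, not negative growth), and positive differences above the
# spurious threshold (default 350 um) are set missing. The spurious test is
# applied to the signed difference before the zero floor, and only positive
# exceedances are spurious: arbitrarily large drops floor to zero, which is
# what keeps a declining (e.g. beetle-infested) tree at SRI = 0 rather than
# discarding its record.

#' Daily maximum stem size
#'
#' @param series long stem-series data.frame (`timestamp`, `site_id`,
#'   `tree_id`, `stem_um`, optional `flag`; readings flagged other than
#'   `"ok"` are ignored).
#' @return data.frame `date`, `site_id`, `tree_id`, `day_max` (um; `NA` when
#'   a day has no usable reading), one row per tree-day in the series span.
#' @export
daily_max <- function(series) {
  dt <- data.table::as.data.table(series)
  if ("flag" %in% names(dt)) dt[flag != "ok", stem_um := NA_real_]
  dt[, date := grid_date(timestamp)]
  out <- dt[, .(day_max = max_na(stem_um)), by = .(site_id, tree_id, date)]
  as.data.frame(out[order(site_id, tree_id, date)])
}

#' Stem Radial Increment from daily maxima
#'
#' Applies the SRI rules per tree over a complete daily calendar (gaps are
#' filled with missing days, never compared across): difference of consecutive
#' daily maxima, missing when the previous day's maximum is unavailable
#' (`basis = "no_previous_max"`), missing when the signed difference exceeds
#' `spurious_threshold` (`basis = "spurious"`; the test is strict, a
#' difference equal to the threshold is retained), otherwise floored at zero
#' (`basis = "ok"`).
#'
#' @param day_max output of [daily_max()] (or any frame with `date`,
#'   `day_max` and optional `site_id`/`tree_id`).
#' @param spurious_threshold spurious-jump threshold (um, default 350).
#' @return data.frame `date`, `site_id`, `tree_id`, `day_max`, `sri`, `basis`.
#' @export
sri <- function(day_max, spurious_threshold = 350) {
  df <- as.data.frame(day_max)
  if (!"tree_id" %in% names(df)) df$tree_id <- "T01"
  if (!"site_id" %in% names(df)) df$site_id <- "S1"
  pieces <- split(df, paste(df$site_id, df$tree_id, sep = "\r"))
  out <- lapply(pieces, function(p) {
    p <- p[order(p$date), , drop = FALSE]
    cal <- data.frame(date = seq(min(p$date), max(p$date), by = "day"),
                      site_id = p$site_id[1], tree_id = p$tree_id[1])
    p <- merge(cal, p[c("date", "day_max")], by = "date", all.x = TRUE)
    prev <- c(NA_real_, p$day_max[-nrow(p)])
    diff <- p$day_max - prev
    sri_val <- ifelse(is.na(diff), NA_real_,
                      ifelse(diff > spurious_threshold, NA_real_,
                             pmax(diff, 0)))
    basis <- ifelse(is.na(diff), "no_previous_max",
                    ifelse(diff > spurious_threshold, "spurious", "ok"))
    p$sri <- sri_val
    p$basis <- basis
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$site_id, out$tree_id, out$date),
      c("date", "site_id", "tree_id", "day_max", "sri", "basis")]
}

#' Site-level SRI across trees
#'
#' Aggregates per-tree daily SRI to one series per site over trees with
#' non-missing values that day (default: arithmetic mean).
#'
#' @param sri_df output of [sri()].
#' @param method `"mean"`, `"median"`, or a tree id to select a single tree.
#' @return data.frame `date`, `site_id`, `sri`, `n_trees`.
#' @export
site_sri <- function(sri_df, method = "mean") {
  dt <- data.table::as.data.table(sri_df)
  if (!method %in% c("mean", "median")) {
    dt <- dt[tree_id == method]
    if (nrow(dt) == 0) stop("no tree with id ", method)
  }
  agg <- if (identical(method, "median")) stats::median else mean
  out <- dt[, .(sri = if (all(is.na(sri))) NA_real_ else
                  agg(sri[!is.na(sri)]),
                n_trees = sum(!is.na(sri))), by = .(site_id, date)]
  as.data.frame(out[order(site_id, date)])
}

#' Cumulative SRI
#'
#' Progressive sum of daily SRI for a single series; missing days contribute
#' zero to the running sum and are counted in the missing-day tally.
#'
#' @param sri_df data.frame with `date` and `sri` for one tree or site.
#' @return data.frame `date`, `sri`, `cum_sri`, `is_missing`; total missing
#'   days in attribute `"n_missing"`.
#' @export
cumulative_sri <- function(sri_df) {
  df <- as.data.frame(sri_df)[order(as.data.frame(sri_df)$date), ]
  miss <- is.na(df$sri)
  out <- data.frame(date = df$date, sri = df$sri,
                    cum_sri = cumsum(ifelse(miss, 0, df$sri)),
                    is_missing = miss)
  attr(out, "n_missing") <- sum(miss)
  out
}

#' Monthly share of annual growth
#'
#' Percentage of the annual total SRI (January 1 to December 31, non-missing
#' days) attributed to each month.
#'
#' @param sri_df data.frame with `date` and `sri` for one tree or site.
#' @param year calendar year to summarize.
#' @return data.frame `month` (1-12), `sri_total` (um), `fraction` (%,
#'   summing to 100 over months with data); all fractions `NA` with a warning
#'   if the annual total is zero.
#' @export
monthly_growth_fraction <- function(sri_df, year) {
  df <- as.data.frame(sri_df)
  yr <- as.POSIXlt(df$date)$year + 1900L
  df <- df[yr == year & !is.na(df$sri), ]
  if (nrow(df) == 0) stop("no non-missing SRI days in ", year)
  mon <- as.POSIXlt(df$date)$mon + 1L
  tot <- vapply(1:12, function(m) sum(df$sri[mon == m]), numeric(1))
  annual <- sum(tot)
  if (annual <= 0) {
    warning("zero annual SRI total in ", year, "; fractions undefined")
    return(data.frame(month = 1:12, sri_total = tot, fraction = NA_real_))
  }
  data.frame(month = 1:12, sri_total = tot, fraction = 100 * tot / annual)
}

#' Growing season from monthly growth fractions
#'
#' The longest run of consecutive calendar months whose growth share strictly
#' exceeds `threshold` percent; ties go to the earliest run, and no
#' wrap-around across the year boundary is attempted.
#'
#' @param fractions twelve monthly percentages (or the output of
#'   [monthly_growth_fraction()]).
#' @param threshold percentage threshold (default 5).
#' @return integer vector of month numbers (possibly empty).
#' @export
growing_season <- function(fractions, threshold = 5) {
  if (is.data.frame(fractions)) fractions <- fractions$fraction
  stopifnot(length(fractions) == 12)
  above <- !is.na(fractions) & fractions > threshold
  r <- rle(above)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the earliest tie
  seq(starts[best], ends[best])
}

#' Growth-onset day from soil temperature
#'
#' First date of the first run of at least `run_length` consecutive days with
#' mean daily soil temperature above `threshold`; a single-day crossing does
#' not trigger onset.
#'
#' @param tsoil_daily data.frame with `date` and `tsoil` (daily mean, C).
#' @param threshold soil-temperature threshold (C, default 5; the field
#'   evidence brackets onset at 4-6 C).
#' @param run_length minimum run of consecutive qualifying days (default 5).
#' @return the onset Date, or `NA` (with a message) if no qualifying run
#'   exists.
#' @export
onset_day <- function(tsoil_daily, threshold = 5, run_length = 5) {
  df <- as.data.frame(tsoil_daily)[order(as.data.frame(tsoil_daily)$date), ]
  cal <- data.frame(date = seq(min(df$date), max(df$date), by = "day"))
  df <- merge(cal, df, by = "date", all.x = TRUE)
  above <- !is.na(df$tsoil) & df$tsoil > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0) {
    message("soil temperature never sustains > ", threshold,
            " C for ", run_length, " days: no onset")
    return(as.Date(NA))
  }
  df$date[starts[hit[1]]]
}

#' Diel-phase decomposition of one day
#'
#' Splits a day's stem-size excursion into the three classical components:
#' contraction (fall from the day's maximum to the subsequent minimum),
#' expansion (recovery from that minimum, capped at the contraction), and
#' increment (`max(0, day_max - prev_max)`, consistent with [sri()]). Phase
#' boundaries are the day's observed extrema, not fixed clock times.
#'
#' @param readings numeric vector of the day's 48 half-hourly stem readings
#'   (`NA` allowed).
#' @param prev_max previous day's maximum stem size (um).
#' @param min_coverage minimum fraction of slots present (default 0.75).
#' @return list `contraction`, `expansion`, `increment` (um), all `NA` when
#'   coverage is insufficient.
#' @export
diel_phases <- function(readings, prev_max, min_coverage = 0.75) {
  if (mean(!is.na(readings)) < min_coverage) {
    return(list(contraction = NA_real_, expansion = NA_real_,
                increment = NA_real_))
  }
  i_max <- which.max(readings)
  day_max <- readings[i_max]
  after <- readings[i_max:length(readings)]
  post_min <- min_na(after)
  contraction <- day_max - post_min
  i_min <- i_max - 1 + which.min(after)
  recovery <- max_na(readings[i_min:length(readings)]) - post_min
  list(contraction = contraction,
       expansion = min(recovery, contraction),
       increment = max(0, day_max - prev_max))
}

#' Dendrometer thermal specification
#'
#' @param sensor_kind `"point"` or `"band"`.
#' @param cte sensor coefficient of thermal expansion (um m-1 C-1); defaults
#'   17 for point sensors, 11.2 for band sensors.
#' @param reference_length expansion reference length (m): the ~10 cm sensing
#'   rod for a point sensor (default 0.1), the stem circumference for a band
#'   (default 1).
#' @param trunk_cte optional trunk coefficient (um m-1 C-1; published conifer
#'   values around -3 to -4).
#' @return object of class `thermal_spec`.
#' @export
thermal_spec <- function(sensor_kind = c("point", "band"), cte = NULL,
                         reference_length = NULL, trunk_cte = NULL) {
  sensor_kind <- match.arg(sensor_kind)
  if (is.null(cte)) cte <- if (sensor_kind == "point") 17 else 11.2
  if (is.null(reference_length)) {
    reference_length <- if (sensor_kind == "point") 0.1 else 1
  }
  if (cte <= 0) stop_invalid("cte", "must be > 0")
  if (reference_length <= 0) stop_invalid("reference_length", "must be > 0")
  structure(list(sensor_kind = sensor_kind, cte = cte,
                 reference_length = reference_length, trunk_cte = trunk_cte),
            class = "thermal_spec")
}

#' Thermal-expansion measurement error
#'
#' Apparent stem-size change induced purely by temperature:
#' `cte * reference_length * delta_t` (um), signed with the temperature
#' change; optionally adds the trunk's own expansion term.
#'
#' @param spec a [thermal_spec()].
#' @param delta_t temperature change (C).
#' @param include_trunk add `trunk_cte * reference_length * delta_t`.
#' @return apparent change (um).
#' @export
thermal_error <- function(spec, delta_t, include_trunk = FALSE) {
  out <- spec$cte * spec$reference_length * delta_t
  if (include_trunk && !is.null(spec$trunk_cte)) {
    out <- out + spec$trunk_cte * spec$reference_length * delta_t
  }
  out
}
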