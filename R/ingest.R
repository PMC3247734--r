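# Half-hourly logger file I/O: delimited text, ISO timestamps, quality flags.
#
# Weather files are wide (one column per channel); dendrometer files are long
# (timestamp, site_id, tree_id, stem_um). Timestamps are naive local standard
# time on the half-hour grid; each stamp labels the interval it closes. Rows
# with unparseable timestamps or non-numeric values are rejected and counted,
# duplicated timestamps keep the first occurrence, and absent grid slots are
# materialized as explicit missing rows so no gap is silent.

WEATHER_CHANNELS <- c("precip", "tair", "tsoil", "soil_moisture", "rh",
                      "pressure", "solrad", "wind_speed", "wind_gust")

fmt_ts <- function(ts) format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out[!is.na(out) & as.numeric(out) %% SLOT_SECONDS != 0] <- NA
  out
}

#' Write a weather or stem logger file
#'
#' Writes delimited text in the same format [read_logger()] reads. Numeric
#' values are written with full precision so a write/read round trip is
#' bit-exact.
#'
#' @param x weather data.frame (wide) or stem series data.frame (long).
#' @param path output file path.
#' @param sep field delimiter.
#' @param missing_token string written for missing values.
#' @return `path`, invisibly.
#' @export
write_logger <- function(x, path, sep = ",", missing_token = "") {
  x <- as.data.frame(x)
  x$timestamp <- fmt_ts(x$timestamp)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    out <- vapply(v, function(z) if (is.na(z)) missing_token else
      format(z, digits = 17, scientific = FALSE), character(1))
    out
  })
  x$flag <- NULL  # flags are a processing product, not a logger channel
  data.table::fwrite(x, path, sep = sep, quote = FALSE, na = missing_token)
  invisible(path)
}

#' Read a half-hourly logger file
#'
#' Parses a delimited logger file onto the half-hour grid. Malformed rows
#' (unparseable timestamp, non-numeric value) are rejected and counted;
#' duplicate timestamps keep the first occurrence; every grid slot between the
#' first and last timestamp is materialized, absent slots as missing. Weather
#' values outside the default physical limits (see [range_check()]) are
#' flagged suspect and set missing.
#'
#' @param path input file path.
#' @param kind `"weather"` or `"stem"`.
#' @param sep field delimiter.
#' @param missing_token string denoting a missing value.
#' @param limits range-check limits for weather files (see [range_check()]);
#'   `NULL` uses the defaults.
#' @return list with `data` (grid-complete data.frame; stem data long with a
#'   `flag` column) and `report` (list: `rows_read`, `rows_rejected`,
#'   `duplicates`, `gaps`, `suspect`).
#' @export
read_logger <- function(path, kind = c("weather", "stem"), sep = ",",
                        missing_token = "", limits = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           na.strings = missing_token, header = TRUE,
                           data.table = FALSE)
  if (nrow(raw) == 0) stop("empty logger file: ", path)
  if (!"timestamp" %in% names(raw)) stop("no 'timestamp' column in ", path)

  rows_read <- nrow(raw)
  ts <- parse_ts(raw$timestamp)
  num_cols <- setdiff(names(raw), c("timestamp", "site_id", "tree_id"))
  vals <- lapply(raw[num_cols], function(v) suppressWarnings(as.numeric(v)))
  bad_num <- if (length(num_cols) == 0) rep(FALSE, rows_read) else
    Reduce(`|`, lapply(seq_along(num_cols), function(j) {
      !is.na(raw[[num_cols[j]]]) & is.na(vals[[j]])
    }))
  ok <- !is.na(ts) & !bad_num
  rows_rejected <- sum(!ok)

  df <- data.frame(timestamp = ts[ok])
  for (j in seq_along(num_cols)) df[[num_cols[j]]] <- vals[[j]][ok]
  if (kind == "stem") {
    df$site_id <- raw$site_id[ok]
    df$tree_id <- raw$tree_id[ok]
  }

  if (kind == "weather") {
    dup <- duplicated(df$timestamp)
    duplicates <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    df <- df[order(df$timestamp), , drop = FALSE]
    full <- data.frame(timestamp = seq(min(df$timestamp), max(df$timestamp),
                                       by = SLOT_SECONDS))
    gaps <- nrow(full) - nrow(df)
    out <- merge(full, df, by = "timestamp", all.x = TRUE, sort = TRUE)
    rc <- range_check(out, limits)
    suspect <- rc$counts
    out <- apply_range_flags(rc)
    report <- list(rows_read = rows_read, rows_rejected = rows_rejected,
                   duplicates = duplicates, gaps = gaps, suspect = suspect)
    return(list(data = out, report = report))
  }

  key <- paste(df$site_id, df$tree_id, fmt_ts(df$timestamp))
  dup <- duplicated(key)
  duplicates <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  pieces <- split(df, paste(df$site_id, df$tree_id, sep = "\r"))
  gaps <- 0L
  out <- lapply(pieces, function(p) {
    p <- p[order(p$timestamp), , drop = FALSE]
    full <- data.frame(timestamp = seq(min(p$timestamp), max(p$timestamp),
                                       by = SLOT_SECONDS),
                       site_id = p$site_id[1], tree_id = p$tree_id[1])
    gaps <<- gaps + nrow(full) - nrow(p)
    m <- merge(full, p[c("timestamp", "stem_um")], by = "timestamp",
               all.x = TRUE, sort = TRUE)
    m$flag <- ifelse(is.na(m$stem_um), "missing", "ok")
    m[c("timestamp", "site_id", "tree_id", "stem_um", "flag")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  report <- list(rows_read = rows_read, rows_rejected = rows_rejected,
                 duplicates = duplicates, gaps = gaps, suspect = 0L)
  list(data = out, report = report)
}

#' Default physical-range limits
#'
#' Inclusive plausibility bounds per weather channel; values outside are
#' flagged suspect (stem-size step screening is deferred to the SRI stage).
#'
#' @return data.frame with columns `variable`, `lo`, `hi`.
#' @export
default_limits <- function() {
  data.frame(variable = c("rh", "tair", "precip", "solrad", "soil_moisture"),
             lo = c(0, -30, 0, 0, 0),
             hi = c(100, 40, Inf, Inf, 100))
}

#' Range-check weather records
#'
#' Flags out-of-range values as suspect without dropping them; bounds are
#' inclusive (a value equal to a limit is in range).
#'
#' @param records weather data.frame.
#' @param limits limits table as from [default_limits()]; `NULL` for defaults.
#' @return list with `records` (untouched), `flags` (logical data.frame, TRUE
#'   = suspect) and `counts` (total suspect values).
#' @export
range_check <- function(records, limits = NULL) {
  if (is.null(limits)) limits <- default_limits()
  flags <- as.data.frame(matrix(FALSE, nrow(records), 0))
  for (i in seq_len(nrow(limits))) {
    v <- limits$variable[i]
    if (!v %in% names(records)) next
    x <- records[[v]]
    flags[[v]] <- !is.na(x) & (x < limits$lo[i] | x > limits$hi[i])
  }
  list(records = records, flags = flags,
       counts = sum(vapply(flags, sum, numeric(1))))
}

#' Treat suspect values as missing
#'
#' @param checked result of [range_check()].
#' @return the records with suspect values set to `NA`.
#' @export
apply_range_flags <- function(checked) {
  out <- checked$records
  for (v in names(checked$flags)) out[[v]][checked$flags[[v]]] <- NA
  out
}
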