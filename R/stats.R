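# Monthly growth-climate response: bootstrapped Pearson correlations and
# principal component regression between site SRI and the twelve daily
# environmental variables, with a percentile-spread significance rule.
#
# For each eligible month (>= 21 pairwise-complete days per variable), 1,000
# day-resamples are drawn with replacement; the statistic is computed on each
# resample and the median estimate is declared significant when its absolute
# value exceeds half the spread between the 97.5th and 2.5th percentiles of
# the resample distribution. All percentiles use empirical order statistics
# with linear interpolation (stats::quantile type 7).

#' Table-order response variables
#'
#' The twelve daily explanatory variables in canonical reporting order, mapped
#' to their [daily_weather()] columns.
#' @return named character vector (names are the report labels).
#' @export
response_variables <- function() {
  c(SolRad = "solrad_total", Prec = "prec_total",
    TSmax = "tsoil_max", TSmin = "tsoil_min",
    TAmax = "tair_max", TAmin = "tair_min",
    RH = "rh_mean", SWV = "soil_moisture_mean", AirPr = "pressure_mean",
    WG = "wind_gust_max", WS = "wind_speed_mean", VPD = "vpd_mean")
}

#' Assemble month panels of paired SRI and weather days
#'
#' Joins a site SRI series to daily weather by date, keeps rows with
#' non-missing SRI, and splits by year-month. Pairwise-complete day counts per
#' variable decide eligibility downstream.
#'
#' @param sri_site data.frame with `date` and `sri` (one site).
#' @param daily output of [daily_weather()].
#' @return list of data.frames, one per year-month (named `"YYYY-MM"`), each
#'   with `date`, `sri` and the twelve response variables.
#' @export
month_panels <- function(sri_site, daily) {
  vars <- response_variables()
  m <- merge(as.data.frame(sri_site)[c("date", "sri")],
             as.data.frame(daily)[c("date", unname(vars))], by = "date")
  m <- m[!is.na(m$sri), , drop = FALSE]
  if (nrow(m) == 0) return(list())
  ym <- format(m$date, "%Y-%m")
  split(m, ym)
}

#' Filter panels on the minimum-days rule
#'
#' Keeps the year-months in which SRI is paired with at least `min_days`
#' non-missing days of at least one variable; per-variable counts are attached
#' so individual variables below the rule are skipped (reported as
#' unavailable) without dropping the month.
#'
#' @param panels output of [month_panels()].
#' @param min_days minimum paired days (default 21, inclusive).
#' @return the retained panels, each with an `"n_days"` attribute (named
#'   per-variable pairwise-complete counts).
#' @export
eligible_months <- function(panels, min_days = 21) {
  vars <- response_variables()
  out <- list()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    n_days <- vapply(unname(vars), function(v) sum(!is.na(p$sri) & !is.na(p[[v]])),
                     integer(1))
    names(n_days) <- names(vars)
    if (max(n_days) >= min_days) {
      attr(p, "n_days") <- n_days
      out[[nm]] <- p
    }
  }
  out
}

draw_resamples <- function(n, n_boot) {
  matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
}

#' Bootstrapped Pearson correlation with percentile-spread significance
#'
#' Resamples day pairs with replacement, computes the Pearson correlation on
#' each resample, and reports the median estimate with its 2.5th/97.5th
#' percentiles. The median is significant when its absolute value exceeds half
#' the percentile spread. Degenerate resamples (zero variance in either
#' margin) are redrawn up to `redraw_cap` times, then counted as failures.
#'
#' @param x,y paired numeric vectors (missing pairs dropped).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resample stream.
#' @param min_n minimum paired sample size (default 21).
#' @param redraw_cap redraw limit for degenerate resamples (default 100).
#' @return list of class `boot_result`: `median_coef`, `q2_5`, `q97_5`,
#'   `half_width`, `significant`, `n`, `n_boot`, `n_degenerate`, `seed`.
#' @export
boot_correlation <- function(x, y, n_boot = 1000, seed = NULL, min_n = 21,
                             redraw_cap = 100) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) stop("insufficient paired observations: ", n, " < ", min_n)
  if (stats::sd(x) == 0) stop("zero variance in x")
  if (stats::sd(y) == 0) stop("zero variance in y")
  with_seed(seed, {
    idx <- draw_resamples(n, n_boot)
    r <- resample_cor(x, y, idx)
    n_degen <- 0L
    bad <- which(is.na(r))
    tries <- 0L
    while (length(bad) > 0 && tries < redraw_cap) {
      idx2 <- draw_resamples(n, length(bad))
      r[bad] <- resample_cor(x, y, idx2)
      bad <- which(is.na(r))
      tries <- tries + 1L
    }
    n_degen <- length(bad)
    r_ok <- r[!is.na(r)]
    summarize_boot(r_ok, n = n, n_boot = n_boot, n_degenerate = n_degen,
                   seed = seed)
  })
}

# Pearson correlation for each resample column of an index matrix (population
# moments cancel the n-1 factors; identical to stats::cor per column)
resample_cor <- function(x, y, idx) {
  xs <- matrix(x[idx], nrow = nrow(idx))
  ys <- matrix(y[idx], nrow = nrow(idx))
  mx <- colMeans(xs); my <- colMeans(ys)
  sxy <- colMeans(xs * ys) - mx * my
  sx <- sqrt(colMeans(xs * xs) - mx^2)
  sy <- sqrt(colMeans(ys * ys) - my^2)
  out <- sxy / (sx * sy)
  out[sx == 0 | sy == 0] <- NA_real_
  out
}

summarize_boot <- function(est, n, n_boot, n_degenerate, seed) {
  q <- stats::quantile(est, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  half_width <- (q[3] - q[1]) / 2
  structure(list(median_coef = q[2], q2_5 = q[1], q97_5 = q[3],
                 half_width = half_width,
                 significant = abs(q[2]) > half_width,
                 n = n, n_boot = n_boot, n_degenerate = n_degenerate,
                 seed = seed),
            class = "boot_result")
}

#' Principal component regression
#'
#' Regresses `y` on the leading principal components of the standardized
#' predictors and back-transforms the coefficients to the original predictor
#' scale. The default selection rule drops components whose eigenvalue of the
#' predictor correlation matrix falls below `eigen_frac` times the mean
#' eigenvalue; it is a clearly-labelled stand-in for the PVP criterion, whose
#' exact formula is not available, and can be swapped via `selection`.
#' Retaining all components (`eigen_frac = 0`) reproduces ordinary least
#' squares on the standardized predictors.
#'
#' @param X numeric matrix or data.frame of predictors (columns named).
#' @param y response vector.
#' @param eigen_frac component-retention fraction of the mean eigenvalue
#'   (default 0.7).
#' @param selection optional function `(eigenvalues) -> logical` of retained
#'   components, overriding the default rule.
#' @return list of class `pcr_fit`: `coef` (original predictor scale),
#'   `coef_std` (standardized scale), `intercept`, `components_retained`,
#'   `selection_rule`.
#' @export
pc_regression <- function(X, y, eigen_frac = 0.7, selection = NULL) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) <= ncol(X)) stop("insufficient rows for ", ncol(X), " predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(X)
  Xs <- scale(X, center = mus, scale = sds)
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  keep_pc <- if (is.null(selection)) {
    e$values >= eigen_frac * mean(e$values)
  } else {
    selection(e$values)
  }
  if (!any(keep_pc)) stop("selection rule retained no components")
  if (any(e$values[keep_pc] < 1e-10)) {
    stop("rank-deficient predictor matrix after component selection")
  }
  V <- e$vectors[, keep_pc, drop = FALSE]
  lam <- e$values[keep_pc]
  n <- nrow(Xs)
  # gamma_k = Z_k'y / ((n-1) * lambda_k), with Z = Xs V
  gamma <- crossprod(V, crossprod(Xs, y)) / ((n - 1) * lam)
  beta_std <- as.numeric(V %*% gamma)
  beta <- beta_std / sds
  names(beta) <- names(beta_std) <- colnames(X)
  structure(list(coef = beta, coef_std = beta_std,
                 intercept = mean(y) - sum(beta * mus),
                 components_retained = sum(keep_pc),
                 selection_rule = if (is.null(selection))
                   sprintf("eigenvalue >= %.2f x mean (PVP stand-in)", eigen_frac)
                 else "custom"),
            class = "pcr_fit")
}

#' Bootstrapped principal component regression
#'
#' Runs [pc_regression()] on each of `n_boot` day-resamples and applies the
#' percentile-spread significance rule to each predictor's coefficient.
#' Resamples on which the fit fails (degenerate predictors) are redrawn up to
#' `redraw_cap` times, then counted.
#'
#' @inheritParams boot_correlation
#' @inheritParams pc_regression
#' @return named list of `boot_result` objects, one per predictor.
#' @export
boot_pcr <- function(X, y, n_boot = 1000, seed = NULL, eigen_frac = 0.7,
                     selection = NULL, min_n = 21, redraw_cap = 100) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  if (n < min_n) stop("insufficient paired observations: ", n, " < ", min_n)
  with_seed(seed, {
    coefs <- matrix(NA_real_, n_boot, ncol(X),
                    dimnames = list(NULL, colnames(X)))
    n_degen <- 0L
    for (b in seq_len(n_boot)) {
      fit <- NULL
      for (attempt in seq_len(redraw_cap)) {
        i <- sample.int(n, n, replace = TRUE)
        fit <- tryCatch(
          suppressWarnings(pc_regression(X[i, , drop = FALSE], y[i],
                                         eigen_frac = eigen_frac,
                                         selection = selection)),
          error = function(e) NULL)
        if (!is.null(fit) && length(fit$coef) == ncol(X)) break
        fit <- NULL
      }
      if (is.null(fit)) n_degen <- n_degen + 1L else coefs[b, ] <- fit$coef
    }
    out <- lapply(colnames(X), function(v) {
      est <- coefs[, v]
      summarize_boot(est[!is.na(est)], n = n, n_boot = n_boot,
                     n_degenerate = n_degen, seed = seed)
    })
    names(out) <- colnames(X)
    out
  })
}

#' Monthly bootstrapped climate response
#'
#' For each eligible year-month and each of the twelve variables with at least
#' `min_days` paired days, runs [boot_correlation()] (and optionally
#' [boot_pcr()] over the jointly complete days) between daily SRI and the
#' variable.
#'
#' @param panels output of [month_panels()].
#' @param n_boot bootstrap resamples per test (default 1000).
#' @param seed integer root seed; each month x variable test receives its own
#'   substream.
#' @param min_days minimum paired days (default 21).
#' @param pcr also run bootstrapped PCR across all twelve predictors.
#' @return long data.frame: `month` ("YYYY-MM"), `variable`, `method`
#'   ("correlation" or "pcr"), `median_coef`, `q2_5`, `q97_5`, `half_width`,
#'   `significant`, `n_days`, `n_boot`, `seed`. Variables with too few days
#'   appear with `NA` estimates (reported as unavailable downstream).
#' @export
boot_climate_response <- function(panels, n_boot = 1000, seed = 1L,
                                  min_days = 21, pcr = FALSE) {
  vars <- response_variables()
  panels <- eligible_months(panels, min_days = min_days)
  rows <- list()
  with_seed(seed, {
    for (nm in names(panels)) {
      p <- panels[[nm]]
      for (v in names(vars)) {
        col <- vars[[v]]
        sub_seed <- sample.int(.Machine$integer.max, 1)
        pair_ok <- !is.na(p$sri) & !is.na(p[[col]])
        n_pair <- sum(pair_ok)
        degenerate <- n_pair > 0 &&
          (stats::sd(p[[col]][pair_ok]) == 0 || stats::sd(p$sri[pair_ok]) == 0)
        if (n_pair < min_days || degenerate) {
          rows[[length(rows) + 1]] <- data.frame(
            month = nm, variable = v, method = "correlation",
            median_coef = NA_real_, q2_5 = NA_real_, q97_5 = NA_real_,
            half_width = NA_real_, significant = NA, n_days = n_pair,
            n_boot = n_boot, seed = sub_seed)
          next
        }
        b <- boot_correlation(p[[col]], p$sri, n_boot = n_boot,
                              seed = sub_seed, min_n = min_days)
        rows[[length(rows) + 1]] <- data.frame(
          month = nm, variable = v, method = "correlation",
          median_coef = b$median_coef, q2_5 = b$q2_5, q97_5 = b$q97_5,
          half_width = b$half_width, significant = b$significant,
          n_days = b$n, n_boot = n_boot, seed = sub_seed)
      }
      if (pcr) {
        Xp <- as.matrix(p[unname(vars)])
        colnames(Xp) <- names(vars)
        cc <- stats::complete.cases(Xp, p$sri)
        if (sum(cc) >= min_days) {
          sub_seed <- sample.int(.Machine$integer.max, 1)
          bp <- tryCatch(boot_pcr(Xp[cc, , drop = FALSE], p$sri[cc],
                                  n_boot = n_boot, seed = sub_seed,
                                  min_n = min_days),
                         error = function(e) NULL)
          if (!is.null(bp)) {
            for (v in names(bp)) {
              b <- bp[[v]]
              rows[[length(rows) + 1]] <- data.frame(
                month = nm, variable = v, method = "pcr",
                median_coef = b$median_coef, q2_5 = b$q2_5, q97_5 = b$q97_5,
                half_width = b$half_width, significant = b$significant,
                n_days = b$n, n_boot = n_boot, seed = sub_seed)
            }
          }
        }
      }
    }
  })
  if (length(rows) == 0) {
    return(data.frame(month = character(), variable = character(),
                      method = character(), median_coef = numeric(),
                      q2_5 = numeric(), q97_5 = numeric(),
                      half_width = numeric(), significant = logical(),
                      n_days = integer(), n_boot = integer(),
                      seed = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Month-by-variable response table
#'
#' Formats bootstrap results as a character matrix in canonical column order:
#' the signed median coefficient (two decimals) when significant, `"ns"` when
#' tested but not significant, `"/"` when the variable was unavailable that
#' month.
#'
#' @param results output of [boot_climate_response()].
#' @param method which results to tabulate (default `"correlation"`).
#' @return character matrix, rows = months ("YYYY-MM"), columns = the twelve
#'   variables.
#' @export
response_table <- function(results, method = "correlation") {
  res <- results[results$method == method, , drop = FALSE]
  months <- sort(unique(res$month))
  vars <- names(response_variables())
  tab <- matrix("/", length(months), length(vars),
                dimnames = list(months, vars))
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    tab[r$month, r$variable] <-
      if (is.na(r$significant)) "/" else
        if (!r$significant) "ns" else sprintf("%.2f", r$median_coef)
  }
  tab
}
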