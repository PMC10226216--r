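#' Daily time-weighted exposure on a working day
#'
#' The personal daily concentration is the duration-weighted mean over five
#' micro-environments: outdoors at home, outdoors at work, indoors at home
#' and at work (outdoor level attenuated by the indoor infiltration factor),
#' and commuting (attenuated by the vehicle factor, with the in-vehicle
#' ambient level taken as the average of the outdoor concentrations at home
#' and work):
#' \deqn{Y = [C_h T_{hout} + C_w T_{wout} + IF_h (C_h T_{hin} + C_w T_{win})
#'   + T_{trans} IF_t (C_h + C_w)/2] / 24}
#'
#' Time budgets summing to 24 +/- 0.5 h are proportionally rescaled to 24
#' (see [normalize_time_budget()]); larger discrepancies are errors.
#'
#' @param c_hout,c_wout Outdoor concentration at the home and work address
#'   (ug/m3; recycled vectors allowed).
#' @param profile One-row `activity_profile` (or list) with `t_hout`,
#'   `t_hin`, `t_wout`, `t_win`, `t_trans` (hours) and `commute_mode`.
#' @param ift An [infiltration_table()].
#' @param pollutant One of [POLLUTANTS].
#' @return Daily exposure(s) Y in the concentration's units.
#' @examples
#' ift <- infiltration_table()
#' p <- list(t_hout = 1, t_hin = 12, t_wout = 1, t_win = 8, t_trans = 2,
#'           commute_mode = "bus")
#' daily_exposure_workday(40, 60, p, ift, "pm25")
#' @export
daily_exposure_workday <- function(c_hout, c_wout, profile, ift, pollutant) {
  .check_conc(c_hout); .check_conc(c_wout)
  p <- .budget_scaled(profile, workday = TRUE)
  ifh <- .if_home(ift, pollutant)
  ift_m <- .if_transit(ift, pollutant, p$commute_mode)
  (c_hout * p$t_hout + c_wout * p$t_wout +
     ifh * (c_hout * p$t_hin + c_wout * p$t_win) +
     p$t_trans * ift_m * (c_hout + c_wout) / 2) / 24
}

#' Daily time-weighted exposure on a day off work
#'
#' On days off the work-place terms drop out and all time is spent around the
#' residence:
#' \deqn{Y = [C_h T_{hout} + IF_h C_h T_{hin} + T_{trans} IF_t C_h] / 24}
#' Work-place hours in the profile are reattributed to the corresponding home
#' micro-environment (indoor work time to indoor home time, outdoor to
#' outdoor) so that the day-off budget also sums to 24 h.
#'
#' @inheritParams daily_exposure_workday
#' @param c_hout Outdoor concentration at the home address.
#' @return Daily exposure(s) Y.
#' @export
daily_exposure_dayoff <- function(c_hout, profile, ift, pollutant) {
  .check_conc(c_hout)
  p <- .budget_scaled(profile, workday = FALSE)
  ifh <- .if_home(ift, pollutant)
  ift_m <- .if_transit(ift, pollutant, p$commute_mode)
  (c_hout * p$t_hout + ifh * c_hout * p$t_hin +
     p$t_trans * ift_m * c_hout) / 24
}

.check_conc <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  invisible(TRUE)
}

.if_home <- function(ift, pollutant) {
  v <- ift$if_home[pollutant]
  if (anyNA(v)) stop("unknown pollutant: ", pollutant)
  unname(v)
}

.if_transit <- function(ift, pollutant, mode) {
  if (!all(mode %in% COMMUTE_MODES))
    stop("unknown commute mode: ", paste(setdiff(mode, COMMUTE_MODES),
                                         collapse = ", "))
  if (!pollutant %in% POLLUTANTS) stop("unknown pollutant: ", pollutant)
  unname(ift$if_transit[mode, pollutant])
}

# rescale one profile's budget to 24 h; for day off, reattribute work hours
# to home and keep commute time
.budget_scaled <- function(profile, workday, tol = 0.5) {
  t <- c(profile$t_hout, profile$t_hin, profile$t_wout, profile$t_win,
         profile$t_trans)
  if (anyNA(t)) stop("time budget contains NA (impute commute time first)")
  if (any(t < 0)) stop("time budget components must be non-negative")
  total <- sum(t)
  if (abs(total - 24) > tol)
    stop("time budget error: components sum to ", round(total, 3),
         " h, outside 24 +/- ", tol)
  t <- t * (24 / total)
  if (workday) {
    list(t_hout = t[1], t_hin = t[2], t_wout = t[3], t_win = t[4],
         t_trans = t[5], commute_mode = profile$commute_mode)
  } else {
    list(t_hout = t[1] + t[3], t_hin = t[2] + t[4], t_wout = 0, t_win = 0,
         t_trans = t[5], commute_mode = profile$commute_mode)
  }
}

# linear coefficients of the daily equations in (c_hout, c_wout); vectorized
# over profile rows. Y_workday = ah*C_h + aw*C_w ; Y_dayoff = bh*C_h
.exposure_coefs <- function(profiles, ift, pollutant, tol = 0.5) {
  tt <- profiles$t_trans
  if (anyNA(tt)) stop("time budget contains NA (impute commute time first)")
  total <- profiles$t_hout + profiles$t_hin + profiles$t_wout +
    profiles$t_win + tt
  bad <- abs(total - 24) > tol
  if (any(bad))
    stop("time budget error for id(s): ",
         paste(utils::head(profiles$id[bad], 5), collapse = ", "))
  s <- 24 / total
  ifh <- .if_home(ift, pollutant)
  iftm <- .if_transit(ift, pollutant, profiles$commute_mode)
  list(
    ah = s * (profiles$t_hout + ifh * profiles$t_hin +
                profiles$t_trans * iftm / 2) / 24,
    aw = s * (profiles$t_wout + ifh * profiles$t_win +
                profiles$t_trans * iftm / 2) / 24,
    bh = s * ((profiles$t_hout + profiles$t_wout) +
                ifh * (profiles$t_hin + profiles$t_win) +
                iftm * profiles$t_trans) / 24
  )
}

#' Trailing-window average of a daily series
#'
#' Arithmetic mean of the daily values over exactly `window` days ending the
#' day *before* the anchor date (the anchor day itself is excluded). The
#' anchor is the diagnosis date for events and the last follow-up date for
#' censored participants.
#'
#' @param values Daily values.
#' @param dates Dates aligned with `values` (consecutive days).
#' @param anchor Anchor date.
#' @param window Window length in days: 365, 730, 1095, 1460 or 1825.
#' @return The window mean.
#' @examples
#' d <- seq(as.Date("2014-01-01"), by = "day", length.out = 730)
#' v <- c(rep(10, 365), rep(20, 365))
#' window_average(v, d, as.Date("2015-12-31") + 1, 365)  # 20
#' window_average(v, d, as.Date("2015-12-31") + 1, 730)  # 15
#' @export
window_average <- function(values, dates, anchor, window) {
  anchor <- as.Date(anchor)
  dates <- as.Date(dates)
  if (length(values) != length(dates)) stop("values/dates length mismatch")
  window <- as.integer(window)
  if (window < 1L) stop("window must be positive")
  lo <- anchor - window
  hi <- anchor - 1L
  sel <- dates >= lo & dates <= hi
  if (sum(sel) != window)
    stop("coverage error: only ", sum(sel), " of ", window,
         " days available before ", format(anchor))
  mean(values[sel])
}

#' Compute time-weighted exposures for a whole cohort
#'
#' For every participant and pollutant, computes the daily time-weighted
#' exposure series over the field's coverage (workday equation on workdays,
#' day-off equation otherwise, per the week schedule) and averages it over
#' each requested trailing window ending the day before the participant's
#' anchor date. Participants with missing home or work coordinates are
#' excluded with a logged reason rather than silently dropped.
#'
#' The computation is vectorized (the daily equations are linear in the two
#' outdoor concentrations, so each participant reduces to two coefficients
#' per day type); [test helpers] compare it against a literal day-by-day
#' scalar loop.
#'
#' @param participants Data frame with `id`, `home_x`, `home_y`, `work_x`,
#'   `work_y` and `index_date` (anchor).
#' @param profiles `activity_profile` data frame aligned by `id` (complete
#'   `t_trans`; run [impute_missing_times()] first if needed).
#' @param field An [field_spec()] object (or anything with a
#'   `concentration_at` method).
#' @param ift An [infiltration_table()].
#' @param windows Integer vector of trailing windows in days
#'   (default `c(365, 730)`).
#' @param pollutants Subset of [POLLUTANTS] to compute (default all).
#' @param workweek Number of workdays per 7-day week (default 5); days off
#'   are the last `7 - workweek` days of each week of the field's coverage.
#' @return Long data frame (`id`, `pollutant`, `window`, `value`) of class
#'   `exposure_table`, with attributes `iqr` (per pollutant x window IQR
#'   summary data frame) and `excluded` (ids + reasons).
#' @export
compute_cohort_exposures <- function(participants, profiles, field, ift,
                                     windows = c(365L, 730L),
                                     pollutants = POLLUTANTS,
                                     workweek = 5L) {
  stopifnot(all(c("id", "home_x", "home_y", "work_x", "work_y",
                  "index_date") %in% names(participants)))
  windows <- sort(unique(as.integer(windows)))

  miss_addr <- is.na(participants$home_x) | is.na(participants$home_y) |
    is.na(participants$work_x) | is.na(participants$work_y)
  excluded <- data.frame(id = participants$id[miss_addr],
                         reason = rep("missing address", sum(miss_addr)))
  if (any(miss_addr)) {
    message("excluding ", sum(miss_addr),
            " participant(s) with missing coordinates")
    participants <- participants[!miss_addr, , drop = FALSE]
  }
  profiles <- profiles[match(participants$id, profiles$id), , drop = FALSE]
  if (anyNA(profiles$id)) stop("profiles missing for some participants")

  anchors <- as.Date(participants$index_date)
  aidx <- as.integer(anchors - field$start) + 1L   # day index of the anchor
  if (any(aidx - max(windows) < 1L))
    stop("coverage error: field history shorter than ", max(windows),
         " days before the earliest anchor (participant ",
         participants$id[which.min(aidx)], ")")
  if (any(aidx > length(field$dates) + 1L))
    stop("coverage error: anchor beyond field coverage")

  is_work <- .workday_indicator(field$dates, workweek)
  n <- nrow(participants)
  out <- vector("list", length(pollutants))
  iqr_rows <- list()

  for (k in seq_along(pollutants)) {
    pol <- pollutants[k]
    Y <- .daily_matrix(participants, profiles, field, ift, pol, is_work)
    # trailing means per participant via row cumulative sums
    cs <- .row_cumsum(Y)
    vals <- lapply(windows, function(w) {
      hi <- aidx - 1L
      lo <- aidx - w
      upper <- cs[cbind(seq_len(n), hi)]
      lower <- ifelse(lo >= 2L, cs[cbind(seq_len(n), pmax(lo - 1L, 1L))], 0)
      (upper - lower) / w
    })
    df <- data.frame(
      id = rep(participants$id, times = length(windows)),
      pollutant = pol,
      window = rep(windows, each = n),
      value = unlist(vals, use.names = FALSE))
    out[[k]] <- df
    iqr_rows[[k]] <- data.frame(
      pollutant = pol, window = windows,
      iqr = vapply(vals, function(v) stats::IQR(v), numeric(1)))
  }
  res <- do.call(rbind, out)
  attr(res, "iqr") <- do.call(rbind, iqr_rows)
  attr(res, "excluded") <- excluded
  class(res) <- c("exposure_table", "data.frame")
  res
}

# workday indicator over calendar days: first `workweek` days of each 7-day
# block counted from the field start are workdays
.workday_indicator <- function(dates, workweek = 5L) {
  if (workweek < 0L || workweek > 7L) stop("workweek must be in 0..7")
  ((seq_along(dates) - 1L) %% 7L) < workweek
}

# n x D matrix of daily exposures for one pollutant
.daily_matrix <- function(participants, profiles, field, ift, pollutant,
                          is_work) {
  co <- .exposure_coefs(profiles, ift, pollutant)
  p <- match(pollutant, POLLUTANTS)
  pr <- field$params[p, ]
  series <- .field_series(field, pollutant)          # length D
  gh <- pr$gx * participants$home_x + pr$gy * participants$home_y  # length n
  gw <- pr$gx * participants$work_x + pr$gy * participants$work_y
  n <- length(gh); D <- length(series)
  S <- matrix(series, n, D, byrow = TRUE)
  Ch <- pmax(S + gh, 0)       # gh recycles down columns
  Cw <- pmax(S + gw, 0)
  Y <- Ch * co$bh             # day-off equation everywhere ...
  wk <- which(is_work)        # ... overwritten on workdays
  Y[, wk] <- Ch[, wk] * co$ah + Cw[, wk] * co$aw
  Y
}

.row_cumsum <- function(m) {
  t(apply(m, 1L, cumsum))
}

#' Per-pollutant IQR summary of an exposure table
#'
#' @param x An `exposure_table` from [compute_cohort_exposures()].
#' @return Data frame `pollutant`, `window`, `iqr`.
#' @export
exposure_iqr <- function(x) {
  iqr <- attr(x, "iqr")
  if (is.null(iqr)) stop("x has no iqr attribute")
  iqr
}

#' Reshape an exposure table to one column per (pollutant, window)
#'
#' Column names are `<pollutant>_<window>`, e.g. `pm25_730`.
#'
#' @param x An `exposure_table`.
#' @return Wide data frame keyed by `id`.
#' @export
exposure_wide <- function(x) {
  x$key <- paste(x$pollutant, x$window, sep = "_")
  wide <- stats::reshape(x[, c("id", "key", "value")], idvar = "id",
                         timevar = "key", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Write an exposure table and its IQR summary
#'
#' @param x An `exposure_table`.
#' @param path CSV path for the long table.
#' @param iqr_path Optional JSON path for the per-pollutant IQR summary.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(x, path, iqr_path = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(iqr_path)) {
    iqr <- exposure_iqr(x)
    jsonlite::write_json(iqr, iqr_path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
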