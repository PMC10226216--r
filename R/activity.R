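#' Decode questionnaire answers into an activity profile
#'
#' Translates the questionnaire's option codes into the numeric time budget
#' used by the exposure equations. The mappings follow the questionnaire's
#' coding conventions:
#'
#' * one-way commute duration options 1 (< 30 min), 2 (30-60 min),
#'   3 (> 60 min) map to 30, 45 and 60 minutes; the round-trip daily commute
#'   is twice the one-way time. A directly reported one-way duration in hours
#'   (`commute_hours`) passes through, doubled. `NA` codes/hours yield an
#'   `NA` `t_trans` to be imputed later.
#' * exercise frequency options 1 (1-2 / week), 2 (3-5 / week),
#'   3 (> 5 / week) map to 2, 4 and 6 sessions per week.
#' * exercise session length options 1 (< 30 min), 2 (30-60 min),
#'   3 (> 60 min) map to 30, 45 and 60 minutes.
#' * exercise venue is decided by the exercise type where given: indoor for
#'   yoga, swimming, gym ball/racket sports; outdoor for jogging, climbing,
#'   bicycling and similar. A `venue` column ("indoor"/"outdoor") may be
#'   supplied directly instead.
#' * commute mode codes 1-4 map to [COMMUTE_MODES] (car/taxi; walk, cycle,
#'   electric bike or motorcycle; bus; subway).
#'
#' Weekly exercise time is spread over the week as `freq * length / 7` hours
#' per day and folded into the home time budget by venue: outdoor exercise
#' time is moved from indoor-at-home to outdoor-at-home; indoor exercise
#' stays within indoor time (no budget change). Directly reported indoor and
#' outdoor hours at home and work pass through unchanged.
#'
#' @param raw Data frame with columns `id`, `t_hin`, `t_hout`, `t_win`,
#'   `t_wout` (hours/day), and either `commute_code` (1-3) or `commute_hours`
#'   (one-way hours); `commute_mode_code` (1-4) or `commute_mode`;
#'   `exercise_freq_code`, `exercise_len_code` (1-3) and one of
#'   `exercise_type` (character) or `exercise_venue` ("indoor"/"outdoor").
#'   Missing exercise columns default to no exercise.
#' @return Data frame of class `activity_profile` with columns `id`,
#'   `t_hout`, `t_hin`, `t_wout`, `t_win`, `t_trans`, `commute_mode`,
#'   `exercise_freq`, `exercise_len`, `exercise_venue`.
#' @examples
#' raw <- data.frame(id = 1, t_hin = 13, t_hout = 1, t_win = 8, t_wout = 0.5,
#'                   commute_code = 2, commute_mode_code = 3,
#'                   exercise_freq_code = 2, exercise_len_code = 2,
#'                   exercise_type = "jogging")
#' decode_questionnaire(raw)
#' @export
decode_questionnaire <- function(raw) {
  raw <- as.data.frame(raw)
  if (!"id" %in% names(raw)) stop("raw must have an 'id' column")
  for (col in c("t_hin", "t_hout", "t_win", "t_wout"))
    if (!col %in% names(raw)) stop("raw must have column '", col, "'")
  n <- nrow(raw)

  commute_min_map <- c(30, 45, 60)       # one-way minutes per option
  if ("commute_hours" %in% names(raw) && any(!is.na(raw$commute_hours))) {
    one_way_h <- raw$commute_hours
    if ("commute_code" %in% names(raw)) {
      use_code <- is.na(one_way_h) & !is.na(raw$commute_code)
      one_way_h[use_code] <- .map_code(raw$commute_code[use_code],
                                       commute_min_map, "commute_code") / 60
    }
  } else if ("commute_code" %in% names(raw)) {
    one_way_h <- ifelse(is.na(raw$commute_code), NA_real_, 0)
    ok <- !is.na(raw$commute_code)
    one_way_h[ok] <- .map_code(raw$commute_code[ok], commute_min_map,
                               "commute_code") / 60
  } else stop("raw must have 'commute_code' or 'commute_hours'")
  t_trans <- 2 * one_way_h   # round trip per day

  if ("commute_mode" %in% names(raw)) {
    mode <- as.character(raw$commute_mode)
    bad <- !is.na(mode) & !(mode %in% COMMUTE_MODES)
    if (any(bad)) stop("unknown commute_mode value(s): ",
                       paste(unique(mode[bad]), collapse = ", "))
  } else if ("commute_mode_code" %in% names(raw)) {
    mode <- COMMUTE_MODES[.map_code(raw$commute_mode_code,
                                    seq_along(COMMUTE_MODES),
                                    "commute_mode_code")]
  } else stop("raw must have 'commute_mode' or 'commute_mode_code'")

  freq <- if ("exercise_freq_code" %in% names(raw))
    .map_code(raw$exercise_freq_code, c(2, 4, 6), "exercise_freq_code",
              na_value = 0) else rep(0, n)
  len_h <- if ("exercise_len_code" %in% names(raw))
    .map_code(raw$exercise_len_code, c(30, 45, 60), "exercise_len_code",
              na_value = 0) / 60 else rep(0, n)

  if ("exercise_venue" %in% names(raw)) {
    venue <- as.character(raw$exercise_venue)
    bad <- !is.na(venue) & !(venue %in% c("indoor", "outdoor"))
    if (any(bad)) stop("exercise_venue must be 'indoor' or 'outdoor'")
  } else if ("exercise_type" %in% names(raw)) {
    venue <- exercise_venue_from_type(raw$exercise_type)
  } else venue <- rep("indoor", n)
  venue[is.na(venue)] <- "indoor"

  t_hout <- raw$t_hout; t_hin <- raw$t_hin
  # fold weekly exercise into the home budget by venue
  ex_daily <- freq * len_h / 7
  shift <- ifelse(venue == "outdoor", pmin(ex_daily, t_hin), 0)
  t_hout <- t_hout + shift
  t_hin <- t_hin - shift

  structure(
    data.frame(id = raw$id, t_hout = t_hout, t_hin = t_hin,
               t_wout = raw$t_wout, t_win = raw$t_win, t_trans = t_trans,
               commute_mode = mode, exercise_freq = freq,
               exercise_len = len_h, exercise_venue = venue,
               stringsAsFactors = FALSE),
    class = c("activity_profile", "data.frame"))
}

.map_code <- function(code, values, what, na_value = NA_real_) {
  code <- as.integer(code)
  out <- rep(na_value, length(code))
  ok <- !is.na(code)
  if (any(ok & (code < 1L | code > length(values))))
    stop("decode error in field '", what, "': unknown option code(s) ",
         paste(unique(code[ok & (code < 1L | code > length(values))]),
               collapse = ", "))
  out[ok] <- values[code[ok]]
  out
}

#' Classify an exercise type as indoor or outdoor
#'
#' Indoor: yoga, swimming, gym-based ball or racket sports, skipping rope.
#' Outdoor: jogging, running, climbing, bicycling, walking, dancing, tai chi.
#'
#' @param type Character vector of exercise type labels.
#' @return Character vector "indoor"/"outdoor" (`NA` passes through).
#' @export
exercise_venue_from_type <- function(type) {
  indoor <- c("yoga", "swimming", "gym", "gym ball sports", "ball sports",
              "racket sports", "skipping rope", "basketball", "badminton",
              "table tennis")
  outdoor <- c("jogging", "running", "climbing", "bicycling", "cycling",
               "walking", "dancing", "tai chi", "hiking")
  t <- tolower(trimws(as.character(type)))
  out <- rep(NA_character_, length(t))
  out[t %in% indoor] <- "indoor"
  out[t %in% outdoor] <- "outdoor"
  unknown <- !is.na(t) & is.na(out) & nzchar(t)
  if (any(unknown))
    stop("decode error in field 'exercise_type': unknown type(s) ",
         paste(unique(t[unknown]), collapse = ", "))
  out
}

#' Normalize a daily time budget to 24 hours
#'
#' The five time-budget components of a workday (outdoor/indoor at home and
#' work plus commuting) must sum to 24 h. Questionnaire sums within
#' 24 +/- `tol` hours are rescaled proportionally to exactly 24; larger
#' discrepancies indicate a data error and abort.
#'
#' @param profile An `activity_profile` data frame.
#' @param tol Tolerance in hours (default 0.5).
#' @return The profile with the five time columns rescaled so each row's
#'   workday budget sums to exactly 24 h.
#' @export
normalize_time_budget <- function(profile, tol = 0.5) {
  cols <- c("t_hout", "t_hin", "t_wout", "t_win", "t_trans")
  tt <- profile$t_trans
  tt[is.na(tt)] <- 0   # missing commute time: rescale the known components
  total <- profile$t_hout + profile$t_hin + profile$t_wout + profile$t_win + tt
  bad <- abs(total - 24) > tol
  if (any(bad))
    stop("time budget error: ", sum(bad), " profile(s) sum to outside 24 +/- ",
         tol, " h (ids: ",
         paste(utils::head(profile$id[bad], 5), collapse = ", "), ")")
  scale <- 24 / total
  for (col in cols) profile[[col]] <- profile[[col]] * scale
  profile
}

#' Impute missing commute times by chained-equation regression
#'
#' Multiple imputation of missing daily commute time (`t_trans`) by the
#' chained-equation recipe specialised to the one incomplete variable: a
#' Bayesian linear regression of `t_trans` on the remaining time-budget and
#' exercise variables plus commute mode is fitted on the complete rows; for
#' each of the `m` imputations the coefficients and residual variance are
#' drawn from their approximate posterior, missing values are predicted, and
#' each prediction is replaced by a predictive-mean-matched donor (nearest
#' `donors` observed values, one sampled), which guarantees imputed values
#' stay within the observed range and non-negative. Because an imputed
#' commute time need not close the reported 24 h day, the imputed rows'
#' remaining time components are rescaled proportionally so the budget
#' closes while the donor commute value is kept exactly.
#'
#' @param activity An `activity_profile` data frame; missingness must be
#'   confined to `t_trans`.
#' @param m Number of completed datasets (default 5).
#' @param donors Donor pool size for predictive mean matching (default 5).
#' @param seed Integer seed.
#' @return List of `m` completed copies of `activity`. With no missing values
#'   all copies are identical to the input.
#' @export
impute_missing_times <- function(activity, m = 5L, donors = 5L, seed = 1L) {
  miss <- is.na(activity$t_trans)
  other <- setdiff(names(activity), "t_trans")
  incomplete_other <- vapply(activity[other], anyNA, logical(1))
  if (any(incomplete_other))
    stop("missingness must be confined to t_trans; also incomplete: ",
         paste(other[incomplete_other], collapse = ", "))
  if (!any(miss)) return(replicate(m, activity, simplify = FALSE))
  if (all(miss)) stop("imputation error: t_trans is 100% missing")

  obs <- activity[!miss, ]
  X <- stats::model.matrix(~ t_hout + t_hin + t_wout + t_win +
                             exercise_freq + exercise_len +
                             factor(commute_mode, levels = COMMUTE_MODES),
                           data = activity)
  y <- activity$t_trans
  Xo <- X[!miss, , drop = FALSE]; yo <- y[!miss]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]   # drop aliased columns
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- length(yo) - length(beta)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xo)))

  .with_seed(seed, {
    lapply(seq_len(m), function(k) {
      sig2 <- s2 * df / stats::rchisq(1, df)
      bstar <- beta + drop(chol(sig2 * XtXinv) %*% stats::rnorm(length(beta)))
      pred_miss <- drop(Xm %*% bstar)
      pred_obs <- drop(Xo %*% bstar)
      filled <- vapply(pred_miss, function(p) {
        pool <- order(abs(pred_obs - p))[seq_len(min(donors, length(pred_obs)))]
        yo[sample(pool, 1L)]
      }, numeric(1))
      out <- activity
      out$t_trans[miss] <- filled
      # an imputed commute time need not close the reported 24 h budget;
      # rescale the imputed rows' remaining components proportionally so the
      # day is coherent while the donor commute value is kept exactly
      cols <- c("t_hout", "t_hin", "t_wout", "t_win")
      tot <- rowSums(out[miss, cols, drop = FALSE])
      scale <- (24 - filled) / tot
      for (cl in cols) out[[cl]][miss] <- out[[cl]][miss] * scale
      out
    })
  })
}

#' Pool estimates across multiple imputations (Rubin's rules)
#'
#' @param est Numeric vector of per-imputation point estimates.
#' @param se Numeric vector of per-imputation standard errors.
#' @return List with `estimate`, `se`, `df` (Barnard-Rubin small-sample
#'   degrees of freedom are not needed here; classical Rubin df returned) and
#'   the between/within variance components.
#' @export
pool_rubin <- function(est, se) {
  stopifnot(length(est) == length(se), length(est) >= 1)
  m <- length(est)
  qbar <- mean(est)
  w <- mean(se^2)
  b <- if (m > 1) stats::var(est) else 0
  total <- w + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  list(estimate = qbar, se = sqrt(total), df = df, within = w, between = b)
}
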