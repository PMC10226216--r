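#' Configuration for a synthetic cohort
#'
#' Defines the study conditions for the seeded generator: cohort size, study
#' calendar, the true exposure effect (log-hazard per unit of the true
#' trailing 2-year time-weighted exposure, per pollutant), baseline hazard,
#' covariate effects on the hazard, and the commute-time missingness
#' fraction.
#'
#' Enrollment starts `history_days` days after `study_start` so that every
#' anchor date has a full exposure history; entry dates are staggered over
#' `enrollment_days`, and follow-up runs to each participant's last attended
#' annual visit (censoring) or event, capped at `study_end`.
#'
#' @param n_participants Cohort size (>= 1).
#' @param study_start,study_end Calendar dates; `study_end` must exceed
#'   `study_start` by at least 730 days.
#' @param history_days Exposure history required before baseline
#'   (default 730, the 2-year window driving the hazard).
#' @param day_off_per_week Days off work per 7-day week (default 2).
#' @param true_log_hr_per_unit Named vector, log-hazard per unit (ug/m3) of
#'   the true trailing 730-day time-weighted exposure; pollutants absent from
#'   the vector have no effect. Default `c(pm25 = 0.05)`.
#' @param baseline_hazard Daily baseline hazard (> 0; the default 6e-5
#'   yields roughly a one-third cumulative incidence over two years of
#'   follow-up at typical exposure levels).
#' @param covariate_effects Named vector of log-hazard effects of
#'   (mean-centred) covariates; supported names: `age`, `male`, `smoker`,
#'   `bmi`. Default `c(age = 0.03, male = 0.3)`.
#' @param enrollment_days Width of the staggered-entry window: entry dates
#'   are uniform over `[baseline, baseline + enrollment_days)` where
#'   baseline is `study_start + history_days` (default 365; 0 enrols
#'   everyone on the baseline day).
#' @param annual_retention Per-year probability of attending the next annual
#'   follow-up visit (default 0.9). Participants without an event are
#'   censored at their last attended visit, so censoring dates vary across
#'   the cohort as in a real checkup cohort; 1 censors everyone at
#'   `study_end`.
#' @param missing_commute_fraction Fraction of commute times set missing
#'   completely at random (default 0.2).
#' @param missing_address_fraction Fraction of participants with a missing
#'   work address (default 0, excluded downstream when positive).
#' @param prevalent_disease_prob Probability of each of the three prevalent
#'   conditions (coronary heart disease, cancer, cerebrovascular disease)
#'   used by the exclusion filter (default 0.02 each).
#' @param field_params,field_corr Optional overrides passed to
#'   [field_spec()].
#' @param seed Integer seed; the single source of randomness.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 3000L,
                          study_start = "2013-01-01",
                          study_end = "2016-12-31",
                          history_days = 730L,
                          day_off_per_week = 2L,
                          true_log_hr_per_unit = c(pm25 = 0.05),
                          enrollment_days = 365L,
                          annual_retention = 0.9,
                          baseline_hazard = 6e-5,
                          covariate_effects = c(age = 0.03, male = 0.3),
                          missing_commute_fraction = 0.2,
                          missing_address_fraction = 0,
                          prevalent_disease_prob = 0.02,
                          field_params = NULL, field_corr = NULL,
                          seed = 1L) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (as.integer(study_end - study_start) < 730L)
    stop("configuration error: study_end must exceed study_start by >= 730 days")
  if (n_participants < 1L) stop("configuration error: n_participants >= 1")
  if (baseline_hazard <= 0) stop("configuration error: baseline_hazard > 0")
  if (missing_commute_fraction < 0 || missing_commute_fraction > 1 ||
      missing_address_fraction < 0 || missing_address_fraction > 1)
    stop("configuration error: proportions must lie in [0, 1]")
  if (day_off_per_week < 0L || day_off_per_week > 7L)
    stop("configuration error: day_off_per_week in 0..7")
  if (as.integer(study_end - study_start) < history_days)
    stop("configuration error: study period shorter than history_days")
  if (history_days < 730L)
    stop("configuration error: history_days must be >= 730 (the trailing ",
         "window driving the hazard)")
  bad <- setdiff(names(true_log_hr_per_unit), POLLUTANTS)
  if (length(bad)) stop("unknown pollutant in true_log_hr_per_unit: ",
                        paste(bad, collapse = ", "))
  if (annual_retention <= 0 || annual_retention > 1)
    stop("configuration error: annual_retention must lie in (0, 1]")
  if (enrollment_days < 0L ||
      as.integer(study_end - study_start) <= history_days + enrollment_days)
    stop("configuration error: enrollment window leaves no follow-up time")
  structure(list(
    n_participants = as.integer(n_participants),
    study_start = study_start, study_end = study_end,
    history_days = as.integer(history_days),
    day_off_per_week = as.integer(day_off_per_week),
    enrollment_days = as.integer(enrollment_days),
    annual_retention = annual_retention,
    true_log_hr_per_unit = true_log_hr_per_unit,
    baseline_hazard = baseline_hazard,
    covariate_effects = covariate_effects,
    missing_commute_fraction = missing_commute_fraction,
    missing_address_fraction = missing_address_fraction,
    prevalent_disease_prob = prevalent_disease_prob,
    field_params = field_params, field_corr = field_corr,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Derive calculated covariates
#'
#' Adds mean arterial pressure (two thirds of diastolic plus one third of
#' systolic pressure, mmHg), body mass index (weight in kg divided by squared
#' height in m) and the sex-specific hyperuricemia flag (serum uric acid
#' >= 360 umol/L in women, >= 420 umol/L in men).
#'
#' @param p Participant data frame with `sbp`, `dbp`, `weight`, `height`,
#'   `ua`, `sex`.
#' @return `p` with columns `map`, `bmi`, `hyperuricemia` added.
#' @examples
#' derive_covariates(data.frame(sbp = 120, dbp = 90, weight = 81,
#'                              height = 1.8, ua = 400, sex = "female"))
#' @export
derive_covariates <- function(p) {
  if (any(p$height <= 0)) stop("domain error: non-positive height")
  if (any(p$dbp <= 0) || any(p$sbp < p$dbp))
    stop("domain error: require SBP >= DBP > 0")
  p$map <- (2 / 3) * p$dbp + (1 / 3) * p$sbp
  p$bmi <- p$weight / p$height^2
  thr <- ifelse(p$sex == "male", 420, 360)
  p$hyperuricemia <- p$ua >= thr
  p
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates a concentration field, participants (demographics, lifestyle,
#' labs, medication flags, home/work coordinates), questionnaire-coded
#' activity profiles, and event times from a piecewise-constant-hazard
#' proportional-hazards model on calendar days whose linear predictor uses
#' the *true* trailing 730-day time-weighted exposure (recomputed each
#' follow-up day) plus centred covariate effects. Entry is staggered over
#' the enrollment window and follow-up runs to each participant's last
#' attended annual visit (per-year retention probability), capped at
#' `study_end`; event times are drawn by inverse-transform sampling within
#' each at-risk interval. The anchor (`index_date`) is the event day for
#' cases and the individual censoring day otherwise.
#'
#' Deterministic given the config seed: the same config yields byte-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return List of class `tw_cohort`: `participants` (data frame incl.
#'   `event_flag`, `index_date`, `follow_days`), `activity`
#'   (`activity_profile`, commute times possibly missing), `field`
#'   (`ambient_field`), `true_exposure` (true 730-day exposure at the anchor
#'   for pollutants with a configured effect), `baseline_date`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  baseline_date <- config$study_start + config$history_days
  fu_days <- as.integer(config$study_end - baseline_date)  # max follow-up
  if (fu_days < 1L) stop("configuration error: no follow-up time")

  field <- field_spec(config$study_start, config$study_end,
                      params = config$field_params, corr = config$field_corr,
                      seed = sample.int(.Machine$integer.max, 1L))

  participants <- .simulate_participants(n, config)
  activity <- .simulate_activity(n)

  # true daily exposure and trailing 730-day means for effect pollutants
  workweek <- 7L - config$day_off_per_week
  is_work <- .workday_indicator(field$dates, workweek)
  beta <- config$true_log_hr_per_unit
  eff_pol <- names(beta)[beta != 0]
  lp <- matrix(0, n, fu_days)
  roll_list <- list()
  for (pol in eff_pol) {
    Y <- .daily_matrix(participants, activity, field, infiltration_table(),
                       pol, is_work)
    cs <- .row_cumsum(Y)
    # hazard on follow-up day t (calendar date baseline + t, field index
    # history_days + t + 1) uses the trailing 730-day mean ending the day
    # before that date -- exactly the anchored window the analysis computes
    hist <- config$history_days
    idx_hi <- hist + seq_len(fu_days)
    idx_lo <- idx_hi - 730L        # >= 1 since history_days >= 730
    roll <- (cs[, idx_hi, drop = FALSE] - cs[, idx_lo, drop = FALSE]) / 730
    roll_list[[pol]] <- roll
    lp <- lp + beta[[pol]] * roll
  }

  cov_lp <- .covariate_lp(participants, config$covariate_effects)
  lp <- lp + cov_lp   # length-n vector recycles down the day columns
  haz <- config$baseline_hazard * exp(lp)

  # staggered entry and per-participant last-visit censoring: entry offsets
  # are uniform over the enrollment window; annual follow-up visits continue
  # with probability annual_retention per year, and participants without an
  # event are censored at their last attended visit (capped at study_end)
  entry <- if (config$enrollment_days > 0L)
    sample.int(config$enrollment_days, n, replace = TRUE) - 1L
  else rep(0L, n)
  years <- if (config$annual_retention < 1)
    1L + stats::rgeom(n, 1 - config$annual_retention) else rep(Inf, n)
  cens <- pmin(entry + 365 * years, fu_days)

  ev <- simulate_event_times(haz, at_risk_start = entry, at_risk_end = cens)
  participants$event_flag <- ev$event
  participants$entry_date <- baseline_date + entry
  participants$index_date <- baseline_date + ev$time
  participants$follow_days <- ev$time - entry
  participants$baseline_date <- baseline_date

  true_exposure <- NULL
  if (length(eff_pol)) {
    true_exposure <- do.call(rbind, lapply(eff_pol, function(pol) {
      data.frame(id = participants$id, pollutant = pol,
                 true_2y = roll_list[[pol]][cbind(seq_len(n), ev$time)])
    }))
  }

  # commute-time MCAR missingness, applied after the truth is computed: the
  # generating exposure used the complete value, the analyst sees the gap
  miss <- stats::runif(n) < config$missing_commute_fraction
  activity$t_trans[miss] <- NA_real_

  if (config$missing_address_fraction > 0) {
    ma <- stats::runif(n) < config$missing_address_fraction
    participants$work_x[ma] <- NA_real_
    participants$work_y[ma] <- NA_real_
  }

  structure(list(participants = participants, activity = activity,
                 field = field, true_exposure = true_exposure,
                 baseline_date = baseline_date, config = config),
            class = "tw_cohort")
}

#' Simulate event times from a daily hazard matrix
#'
#' Inverse-transform sampling from a piecewise-constant (per-day) hazard:
#' participant i is at risk on days `at_risk_start[i] + 1` to
#' `at_risk_end[i]`, has an event on the first at-risk day at which their
#' cumulative hazard reaches an exponential threshold, and is censored at
#' `at_risk_end[i]` otherwise.
#'
#' @param haz n x D matrix of daily hazards (D = grid days after baseline).
#' @param at_risk_start Integer vector of entry offsets (0 = at risk from
#'   day 1); default all 0.
#' @param at_risk_end Integer vector of last at-risk days (default all D).
#' @return List with integer `time` (day offset of the event or censoring,
#'   in 1..D) and `event` (0/1) vectors.
#' @export
simulate_event_times <- function(haz, at_risk_start = NULL,
                                 at_risk_end = NULL) {
  if (any(haz < 0)) stop("negative hazards")
  n <- nrow(haz); D <- ncol(haz)
  if (is.null(at_risk_start)) at_risk_start <- rep(0L, n)
  if (is.null(at_risk_end)) at_risk_end <- rep(D, n)
  at_risk_end <- pmin(at_risk_end, D)
  if (any(at_risk_start >= at_risk_end))
    stop("at_risk_start must precede at_risk_end")
  H <- .row_cumsum(haz)
  Hstart <- ifelse(at_risk_start >= 1L,
                   H[cbind(seq_len(n), pmax(at_risk_start, 1L))], 0)
  e <- stats::rexp(n)
  # prefix length with cumulative at-risk hazard below the threshold
  before <- rowSums(H < e + Hstart)
  event <- as.integer(before + 1L <= at_risk_end)
  time <- as.integer(pmin(before + 1L, at_risk_end))
  list(time = time, event = event)
}

.covariate_lp <- function(participants, effects) {
  if (!length(effects)) return(rep(0, nrow(participants)))
  vals <- sapply(names(effects), function(nm) {
    v <- switch(nm,
                age = participants$age,
                male = as.numeric(participants$sex == "male"),
                smoker = as.numeric(participants$smoker),
                bmi = participants$bmi,
                stop("unsupported covariate effect: ", nm))
    v - mean(v)
  })
  drop(as.matrix(vals) %*% unname(effects))
}

# margins loosely follow an urban health-checkup cohort
.simulate_participants <- function(n, config) {
  sex <- ifelse(stats::runif(n) < 0.463, "male", "female")
  age <- round(pmin(75, pmax(25, stats::rnorm(n, 42, 10))))
  education <- sample(c("high_school_or_less", "college", "postgraduate"),
                      n, replace = TRUE, prob = c(0.0704, 0.7634, 0.1662))
  activity_intensity <- sample(c("low", "moderate", "high"), n, replace = TRUE,
                               prob = c(0.6403, 0.3007, 0.0590))
  smoker <- stats::runif(n) < 0.1887
  drinker <- stats::runif(n) < 0.3737
  excess_salt <- stats::runif(n) < 0.2704
  med_hypertension <- stats::runif(n) < 0.1193
  med_diabetes <- stats::runif(n) < 0.0381
  med_dyslipidemia <- stats::runif(n) < 0.0381
  dbp <- pmax(50, stats::rnorm(n, 78, 9))
  sbp <- dbp + pmax(15, stats::rnorm(n, 42, 10))
  height <- ifelse(sex == "male", stats::rnorm(n, 1.72, 0.06),
                   stats::rnorm(n, 1.60, 0.055))
  bmi0 <- pmax(16, stats::rnorm(n, 24.2, 3.2))
  weight <- bmi0 * height^2
  fbg <- pmax(3.5, exp(stats::rnorm(n, log(5.2), 0.10)))
  ldl <- pmax(0.8, stats::rnorm(n, 2.75, 0.70))
  hdl <- pmax(0.5, stats::rnorm(n, 1.35, 0.33))
  tg <- pmax(0.3, exp(stats::rnorm(n, log(1.2), 0.50)))
  ua <- pmax(100, ifelse(sex == "male", stats::rnorm(n, 350, 70),
                         stats::rnorm(n, 260, 60)))
  # planar km coordinates on a 30 km square; work clusters nearer the centre
  home_x <- stats::runif(n, 0, 30); home_y <- stats::runif(n, 0, 30)
  work_x <- pmin(30, pmax(0, stats::rnorm(n, 15, 6)))
  work_y <- pmin(30, pmax(0, stats::rnorm(n, 15, 6)))
  prevalent_disease <- stats::runif(n) < (1 - (1 - config$prevalent_disease_prob)^3)

  df <- data.frame(
    id = seq_len(n), age = age, sex = sex, education = education,
    activity_intensity = activity_intensity, smoker = smoker,
    drinker = drinker, excess_salt = excess_salt,
    med_hypertension = med_hypertension, med_diabetes = med_diabetes,
    med_dyslipidemia = med_dyslipidemia,
    sbp = sbp, dbp = dbp, weight = weight, height = height,
    fbg = fbg, ldl = ldl, hdl = hdl, tg = tg, ua = ua,
    home_x = home_x, home_y = home_y, work_x = work_x, work_y = work_y,
    prevalent_disease = prevalent_disease,
    stringsAsFactors = FALSE)
  derive_covariates(df)
}

.simulate_activity <- function(n) {
  raw <- data.frame(
    id = seq_len(n),
    t_hout = pmax(0.25, stats::rnorm(n, 1.25, 0.5)),
    t_win = pmax(4, stats::rnorm(n, 8, 1)),
    t_wout = pmax(0, stats::rnorm(n, 0.5, 0.25)),
    commute_code = sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20)),
    commute_mode_code = sample(1:4, n, replace = TRUE,
                               prob = c(0.35, 0.20, 0.25, 0.20)),
    exercise_freq_code = sample(1:3, n, replace = TRUE,
                                prob = c(0.50, 0.35, 0.15)),
    exercise_len_code = sample(1:3, n, replace = TRUE,
                               prob = c(0.35, 0.45, 0.20)),
    exercise_venue = sample(c("indoor", "outdoor"), n, replace = TRUE,
                            prob = c(0.4, 0.6)))
  # indoor home time roughly closes the 24 h budget; questionnaire sums
  # carry reporting noise within the +/- 0.5 h normalization tolerance
  t_trans <- 2 * c(30, 45, 60)[raw$commute_code] / 60
  raw$t_hin <- 24 - raw$t_hout - raw$t_win - raw$t_wout - t_trans +
    pmin(0.45, pmax(-0.45, stats::rnorm(n, 0, 0.15)))
  decode_questionnaire(raw)
}

#' @export
print.tw_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf(
    "Synthetic cohort: n = %d, events = %d (%.1f%%), baseline %s, end %s\n",
    nrow(p), sum(p$event_flag), 100 * mean(p$event_flag),
    format(x$baseline_date), format(x$config$study_end)))
  cat(sprintf("  commute time missing: %d (%.1f%%); seed %d\n",
              sum(is.na(x$activity$t_trans)),
              100 * mean(is.na(x$activity$t_trans)), x$config$seed))
  invisible(x)
}

#' Write cohort and activity tables as CSV
#'
#' @param cohort A `tw_cohort`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- file.path(dir, "participants.csv")
  ac <- file.path(dir, "activity.csv")
  utils::write.csv(cohort$participants, pc, row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$activity), ac, row.names = FALSE)
  invisible(c(pc, ac))
}
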