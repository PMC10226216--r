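# Independent oracles used across the suite. These deliberately mirror the
# definitions, not the package implementation.

# Efron-tie Cox partial log-likelihood from explicit risk sets
efron_loglik <- function(beta, X, time, status) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (tau in sort(unique(time[status == 1]))) {
    D <- which(time == tau & status == 1)
    R <- which(time >= tau)
    m <- length(D)
    s0r <- sum(w[R]); s0d <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(m) - 1) ll <- ll - log(s0r - (l / m) * s0d)
  }
  ll
}

# Efron score vector (gradient of the partial log-likelihood)
efron_score <- function(beta, X, time, status) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  U <- numeric(ncol(X))
  for (tau in sort(unique(time[status == 1]))) {
    D <- which(time == tau & status == 1)
    R <- which(time >= tau)
    m <- length(D)
    s0r <- sum(w[R]); s0d <- sum(w[D])
    s1r <- colSums(X[R, , drop = FALSE] * w[R])
    s1d <- colSums(X[D, , drop = FALSE] * w[D])
    U <- U + colSums(X[D, , drop = FALSE])
    for (l in seq_len(m) - 1)
      U <- U - (s1r - (l / m) * s1d) / (s0r - (l / m) * s0d)
  }
  U
}

# literal day-by-day scalar reference for one participant's exposure series:
# loops over calendar days, applying the workday or day-off equation to that
# day's looked-up concentrations
scalar_exposure_series <- function(participant, profile, field, ift,
                                   pollutant, workweek = 5L) {
  dates <- field$dates
  ch_all <- concentration_at(field, pollutant,
                             c(participant$home_x, participant$home_y), dates)
  cw_all <- concentration_at(field, pollutant,
                             c(participant$work_x, participant$work_y), dates)
  out <- numeric(length(dates))
  for (d in seq_along(dates)) {
    if (((d - 1L) %% 7L) < workweek) {
      out[d] <- daily_exposure_workday(ch_all[d], cw_all[d], profile, ift,
                                       pollutant)
    } else {
      out[d] <- daily_exposure_dayoff(ch_all[d], profile, ift, pollutant)
    }
  }
  out
}

# a valid random activity profile row (workday budget sums to 24 h)
random_profile <- function(mode = sample(COMMUTE_MODES, 1)) {
  t <- c(runif(1, 0, 3), runif(1, 4, 16), runif(1, 0, 2), runif(1, 2, 10),
         runif(1, 0.2, 3))
  t <- t * 24 / sum(t)
  list(t_hout = t[1], t_hin = t[2], t_wout = t[3], t_win = t[4],
       t_trans = t[5], commute_mode = mode)
}

# small analysis-ready data frame: continuous exposure, minimal covariates,
# exponential event times with log-linear hazard beta_per_unit * exposure
sim_survival_data <- function(n, beta_per_unit, fu_days = 730,
                              base_haz = 5e-4, exposure_sd = 4,
                              exposure_mean = 42) {
  x <- rnorm(n, exposure_mean, exposure_sd)
  age <- round(runif(n, 30, 70))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  lp <- beta_per_unit * (x - exposure_mean) + 0.02 * (age - 50) +
    0.2 * (sex == "male")
  t_event <- rexp(n, rate = base_haz * exp(lp))
  event <- as.integer(t_event <= fu_days)
  data.frame(exposure = x, age = age, sex = sex,
             follow_days = ceiling(pmin(t_event, fu_days)),
             event_flag = event)
}

# add the remaining Model-3 covariates (independent noise) so the full
# covariate sets can be exercised on simulated data
add_model3_covariates <- function(d) {
  n <- nrow(d)
  d$education <- sample(c("high_school_or_less", "college", "postgraduate"),
                        n, replace = TRUE)
  d$activity_intensity <- sample(c("low", "moderate", "high"), n,
                                 replace = TRUE)
  d$smoker <- runif(n) < 0.2
  d$drinker <- runif(n) < 0.35
  d$excess_salt <- runif(n) < 0.3
  d$med_hypertension <- runif(n) < 0.12
  d$med_diabetes <- runif(n) < 0.04
  d$med_dyslipidemia <- runif(n) < 0.04
  d$bmi <- rnorm(n, 24, 3)
  d$map <- rnorm(n, 90, 8)
  d$fbg <- rnorm(n, 5.2, 0.5)
  d$ua <- rnorm(n, 300, 70)
  d$ldl <- rnorm(n, 2.7, 0.6)
  d$hdl <- rnorm(n, 1.3, 0.3)
  d$tg <- rnorm(n, 1.3, 0.5)
  d
}

# compact cohort config for fast end-to-end runs: short follow-up, narrow
# enrollment window, raised baseline hazard so small cohorts still carry a
# workable number of events
small_cohort_config <- function(n = 250, seed = 1, ...) {
  defaults <- list(n_participants = n, study_start = "2013-01-01",
                   study_end = "2015-06-30", enrollment_days = 120L,
                   baseline_hazard = 5e-4, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
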