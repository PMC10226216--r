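make_raw <- function(...) {
  base <- data.frame(id = 1, t_hin = 13, t_hout = 1, t_win = 8, t_wout = 0.5,
                     commute_code = 2, commute_mode_code = 3,
                     exercise_freq_code = NA, exercise_len_code = NA)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("questionnaire option codes decode to the standard values", {
  # commute option 2 (30-60 min) -> 45 min one way -> 1.5 h/day round trip
  p <- decode_questionnaire(make_raw(commute_code = 2))
  expect_equal(p$t_trans, 1.5)
  expect_equal(decode_questionnaire(make_raw(commute_code = 1))$t_trans, 1.0)
  expect_equal(decode_questionnaire(make_raw(commute_code = 3))$t_trans, 2.0)
  expect_equal(p$commute_mode, "bus")

  # exercise frequency option 3 (>5 / week) -> 6 sessions
  p <- decode_questionnaire(make_raw(exercise_freq_code = 3,
                                     exercise_len_code = 1,
                                     exercise_venue = "indoor"))
  expect_equal(p$exercise_freq, 6)
  expect_equal(p$exercise_len, 0.5)

  # directly reported 0.5 h one-way doubles to 1 h/day
  p <- decode_questionnaire(make_raw(commute_code = NULL,
                                     commute_hours = 0.5))
  expect_equal(p$t_trans, 1.0)

  expect_error(decode_questionnaire(make_raw(commute_code = 7)),
               "commute_code")
  expect_error(decode_questionnaire(make_raw(exercise_freq_code = 9,
                                             exercise_len_code = 1)),
               "exercise_freq_code")
})

test_that("exercise venue follows the exercise type", {
  expect_equal(exercise_venue_from_type(c("yoga", "jogging", "swimming",
                                          "bicycling", "climbing")),
               c("indoor", "outdoor", "indoor", "outdoor", "outdoor"))
  expect_error(exercise_venue_from_type("knitting"), "exercise_type")
})

test_that("outdoor exercise shifts home time from indoors to outdoors", {
  raw <- make_raw(exercise_freq_code = 2, exercise_len_code = 3,
                  exercise_type = "jogging")
  p <- decode_questionnaire(raw)
  shift <- 4 * 1 / 7                       # 4 sessions x 60 min over 7 days
  expect_equal(p$t_hout, 1 + shift)
  expect_equal(p$t_hin, 13 - shift)
  # total budget preserved
  expect_equal(p$t_hout + p$t_hin, 14)

  # indoor exercise leaves the split unchanged
  pin <- decode_questionnaire(make_raw(exercise_freq_code = 2,
                                       exercise_len_code = 3,
                                       exercise_type = "yoga"))
  expect_equal(pin$t_hout, 1)
  expect_equal(pin$t_hin, 13)
})

test_that("time budgets are rescaled within tolerance and rejected beyond", {
  p <- decode_questionnaire(make_raw())      # sums to 24 exactly
  expect_equal(normalize_time_budget(p)$t_hin, p$t_hin)

  p2 <- p; p2$t_hin <- p2$t_hin + 0.4        # 24.4 -> rescale
  n2 <- normalize_time_budget(p2)
  expect_equal(n2$t_hout + n2$t_hin + n2$t_wout + n2$t_win + n2$t_trans, 24)
  expect_equal(n2$t_hin / n2$t_hout, p2$t_hin / p2$t_hout)

  p3 <- p; p3$t_hin <- p3$t_hin + 2
  expect_error(normalize_time_budget(p3), "time budget")
})

sim_activity_with_missing <- function(n, miss_frac, seed = 4) {
  set.seed(seed)
  raw <- data.frame(
    id = seq_len(n),
    t_hout = runif(n, 0.5, 2), t_win = runif(n, 6, 9),
    t_wout = runif(n, 0, 1),
    commute_code = sample(1:3, n, TRUE),
    commute_mode_code = sample(1:4, n, TRUE),
    exercise_freq_code = sample(1:3, n, TRUE),
    exercise_len_code = sample(1:3, n, TRUE),
    exercise_venue = sample(c("indoor", "outdoor"), n, TRUE))
  t_trans <- 2 * c(30, 45, 60)[raw$commute_code] / 60
  raw$t_hin <- 24 - raw$t_hout - raw$t_win - raw$t_wout - t_trans +
    runif(n, -0.3, 0.3)                    # imperfect questionnaire sums
  act <- decode_questionnaire(raw)
  act$t_trans[seq_len(floor(n * miss_frac))] <- NA
  act
}

test_that("imputation returns identical copies when nothing is missing", {
  act <- sim_activity_with_missing(40, 0)
  imp <- impute_missing_times(act, m = 5, seed = 1)
  expect_length(imp, 5)
  for (k in 1:5) expect_identical(imp[[k]], act)
})

test_that("imputed commute times stay within the observed range", {
  act <- sim_activity_with_missing(500, 0.002)   # one missing value
  imp <- impute_missing_times(act, m = 5, seed = 2)
  obs <- act$t_trans[!is.na(act$t_trans)]
  for (k in 1:5) {
    v <- imp[[k]]$t_trans[is.na(act$t_trans)]
    expect_false(anyNA(v))
    expect_gte(v, min(obs))
    expect_lte(v, max(obs))
  }

  act2 <- sim_activity_with_missing(200, 0.2)
  imp2 <- impute_missing_times(act2, m = 5, seed = 3)
  obs2 <- act2$t_trans[!is.na(act2$t_trans)]
  for (k in 1:5) {
    v <- imp2[[k]]$t_trans[is.na(act2$t_trans)]
    expect_true(all(v >= min(obs2)) && all(v <= max(obs2)))
  }
  # different imputations differ somewhere (they are random draws)
  expect_false(identical(imp2[[1]]$t_trans, imp2[[2]]$t_trans))
  # seeded: same call reproduces
  imp2b <- impute_missing_times(act2, m = 5, seed = 3)
  expect_identical(imp2, imp2b)
})

test_that("fully missing commute time is an error", {
  act <- sim_activity_with_missing(30, 0)
  act$t_trans <- NA_real_
  expect_error(impute_missing_times(act), "100% missing")
})

test_that("Rubin pooling reproduces the textbook arithmetic", {
  est <- c(1.0, 1.2, 0.9)
  se <- c(0.30, 0.32, 0.28)
  pl <- pool_rubin(est, se)
  expect_equal(pl$estimate, mean(est))
  expect_equal(pl$se, sqrt(mean(se^2) + (1 + 1 / 3) * var(est)))
})
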