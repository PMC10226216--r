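# fully controllable infiltration table for oracle arithmetic
ift_with <- function(ifh, ift_mode) {
  infiltration_table(
    if_home = setNames(rep(ifh, 6), POLLUTANTS),
    if_transit = matrix(ift_mode, 4, 6,
                        dimnames = list(COMMUTE_MODES, POLLUTANTS)))
}

test_that("workday equation reproduces hand arithmetic", {
  # C_h=40, C_w=60, T_hout=1, T_wout=1, T_hin=12, T_win=8, T_trans=2,
  # IF_h=0.5, IF_t=0.6:
  # 40*1 + 60*1 + 0.5*(40*12 + 60*8) + 2*0.6*(40+60)/2 = 640; /24
  p <- list(t_hout = 1, t_hin = 12, t_wout = 1, t_win = 8, t_trans = 2,
            commute_mode = "car")
  y <- daily_exposure_workday(40, 60, p, ift_with(0.5, 0.6), "pm25")
  expect_equal(y, 640 / 24, tolerance = 1e-12)

  # homogeneous field with no attenuation: Y equals the field value
  for (i in 1:5) {
    pr <- random_profile()
    expect_equal(daily_exposure_workday(37.5, 37.5, pr, ift_with(1, 1),
                                        "pm10"),
                 37.5, tolerance = 1e-12)
  }

  # single-term limit: all day indoors at home
  p1 <- list(t_hout = 0, t_hin = 24, t_wout = 0, t_win = 0, t_trans = 0,
             commute_mode = "car")
  expect_equal(daily_exposure_workday(50, 80, p1, ift_with(0.5, 0.9), "so2"),
               25, tolerance = 1e-12)
})

test_that("day-off equation reproduces hand arithmetic", {
  # C_h=30, T_hout=2, T_hin=21, T_trans=1, IF_h=0.5, IF_t=0.8:
  # (60 + 315 + 24)/24 = 16.625
  p <- list(t_hout = 2, t_hin = 21, t_wout = 0, t_win = 0, t_trans = 1,
            commute_mode = "bus")
  y <- daily_exposure_dayoff(30, p, ift_with(0.5, 0.8), "no2")
  expect_equal(y, 16.625, tolerance = 1e-12)

  # no attenuation and a 24 h budget: Y equals the ambient level
  pr <- random_profile()
  expect_equal(daily_exposure_dayoff(61.2, pr, ift_with(1, 1), "o3"), 61.2,
               tolerance = 1e-12)

  # zero field
  expect_equal(daily_exposure_dayoff(0, p, ift_with(0.5, 0.8), "co"), 0)
  expect_error(daily_exposure_dayoff(-1, p, ift_with(0.5, 0.8), "co"),
               "non-negative")
})

test_that("exposure invariants hold over random valid inputs", {
  set.seed(801)
  n_bad_convex <- 0
  for (i in 1:1000) {
    pr <- random_profile()
    ifh <- runif(1, 0.05, 1); ifv <- runif(1, 0.05, 1)
    ift <- ift_with(ifh, ifv)
    ch <- runif(1, 0, 150); cw <- runif(1, 0, 150)
    y <- daily_exposure_workday(ch, cw, pr, ift, "pm25")
    # convexity bound
    expect_lte(y, max(ch, cw) + 1e-12)
    expect_gte(y, min(ifh, ifv) * min(ch, cw) - 1e-12)
    # with IF = 1 the result is a convex combination
    y1 <- daily_exposure_workday(ch, cw, pr, ift_with(1, 1), "pm25")
    expect_lte(y1, max(ch, cw) + 1e-12)
    expect_gte(y1, min(ch, cw) - 1e-12)
    # pointwise dominance of the no-infiltration variant
    expect_gte(y1, y - 1e-12)
    # monotone in each concentration
    expect_gte(daily_exposure_workday(ch + 5, cw, pr, ift, "pm25"), y)
    expect_gte(daily_exposure_workday(ch, cw + 5, pr, ift, "pm25"), y)
    # monotone in the infiltration factors
    ifh2 <- min(1, ifh + 0.1); ifv2 <- min(1, ifv + 0.1)
    expect_gte(daily_exposure_workday(ch, cw, pr, ift_with(ifh2, ifv), "pm25"), y)
    expect_gte(daily_exposure_workday(ch, cw, pr, ift_with(ifh, ifv2), "pm25"), y)
  }
})

test_that("window averages follow the trailing-window definition", {
  d <- seq(as.Date("2014-01-01"), by = "day", length.out = 730)
  anchor <- d[730] + 1

  expect_equal(window_average(rep(7.5, 730), d, anchor, 365), 7.5)
  expect_equal(window_average(rep(7.5, 730), d, anchor, 730), 7.5)

  v <- c(rep(10, 365), rep(20, 365))
  expect_equal(window_average(v, d, anchor, 365), 20)
  expect_equal(window_average(v, d, anchor, 730), 15)

  expect_equal(window_average(rep(c(0, 10), 365), d, anchor, 730), 5)

  # anchor day itself is excluded
  v2 <- c(rep(0, 729), 1000)
  expect_equal(window_average(v2, d, d[730], 365), 0)

  expect_error(window_average(v, d, anchor, 1095), "coverage")
})

test_that("cohort computation matches the scalar day-loop reference", {
  set.seed(77)
  cfg <- small_cohort_config(n = 50, seed = 77, missing_commute_fraction = 0)
  coh <- simulate_cohort(cfg)
  ift <- infiltration_table()
  expo <- compute_cohort_exposures(coh$participants, coh$activity, coh$field,
                                   ift, windows = c(365, 730),
                                   pollutants = c("pm25", "o3"))
  for (i in sample(50, 50)) {
    part <- coh$participants[i, ]
    prof <- coh$activity[coh$activity$id == part$id, ]
    for (pol in c("pm25", "o3")) {
      ref_series <- scalar_exposure_series(part, prof, coh$field, ift, pol)
      for (w in c(365, 730)) {
        ref <- window_average(ref_series, coh$field$dates, part$index_date, w)
        got <- expo$value[expo$id == part$id & expo$pollutant == pol &
                            expo$window == w]
        expect_equal(got, ref, tolerance = 1e-9)
      }
    }
  }
})

test_that("cohort exposure trivial limits hold", {
  # homogeneous constant field, IF = 1 -> every window equals the constant
  pars <- default_field_params()
  pars$amplitude <- 0; pars$gx <- 0; pars$gy <- 0; pars$noise_sd <- 0
  cfg <- small_cohort_config(n = 20, seed = 5, missing_commute_fraction = 0,
                             field_params = pars)
  coh <- simulate_cohort(cfg)
  expo <- compute_cohort_exposures(coh$participants, coh$activity, coh$field,
                                   infiltration_unit(), windows = c(365, 730),
                                   pollutants = "pm25")
  expect_equal(expo$value, rep(60, nrow(expo)), tolerance = 1e-9)

  # all time indoors at home with IF_h < 1 -> exposure = IF_h * C_hout
  act <- coh$activity
  act$t_hout <- 0; act$t_wout <- 0; act$t_win <- 0; act$t_trans <- 0
  act$t_hin <- 24
  ift <- ift_with(0.5, 0.7)
  expo2 <- compute_cohort_exposures(coh$participants, act, coh$field, ift,
                                    windows = 365, pollutants = "pm25")
  expect_equal(expo2$value, rep(0.5 * 60, nrow(expo2)), tolerance = 1e-9)
})

test_that("mixed work/day-off schedule matches a hand-computed weighted mean", {
  # constant-in-time field with a spatial gradient so home and work differ
  pars <- default_field_params()
  pars$amplitude <- 0; pars$noise_sd <- 0
  fld <- field_spec("2014-01-01", "2014-12-31", params = pars, seed = 1)
  part <- data.frame(id = 1L, home_x = 0, home_y = 0, work_x = 10, work_y = 0,
                     index_date = as.Date("2014-06-01"))
  prof <- data.frame(id = 1L, t_hout = 2, t_hin = 12, t_wout = 1, t_win = 8,
                     t_trans = 1, commute_mode = "subway",
                     exercise_freq = 0, exercise_len = 0,
                     exercise_venue = "indoor")
  ift <- ift_with(0.5, 0.6)
  ch <- 60                                  # pm25 at origin
  cw <- 60 + 0.5 * 10                       # gradient gx = 0.5 per km
  y_work <- (ch * 2 + cw * 1 + 0.5 * (ch * 12 + cw * 8) +
               1 * 0.6 * (ch + cw) / 2) / 24
  y_off <- (ch * 3 + 0.5 * ch * 20 + 1 * 0.6 * ch) / 24
  # 14-day window: two full weeks of 5 workdays + 2 days off
  expect_ref <- (10 * y_work + 4 * y_off) / 14
  expo <- compute_cohort_exposures(part, prof, fld, ift, windows = 14,
                                   pollutants = "pm25")
  expect_equal(expo$value, expect_ref, tolerance = 1e-12)
})

test_that("missing addresses are excluded with a reason", {
  cfg <- small_cohort_config(n = 30, seed = 9, missing_commute_fraction = 0)
  coh <- simulate_cohort(cfg)
  p <- coh$participants
  p$work_x[c(3, 7)] <- NA
  expect_message(
    expo <- compute_cohort_exposures(p, coh$activity, coh$field,
                                     infiltration_table(), windows = 365,
                                     pollutants = "pm25"),
    "excluding 2")
  excl <- attr(expo, "excluded")
  expect_equal(excl$id, p$id[c(3, 7)])
  expect_false(any(expo$id %in% excl$id))
  expect_equal(length(unique(expo$id)), 28)
})

test_that("the IQR summary reflects the computed distribution", {
  cfg <- small_cohort_config(n = 60, seed = 12, missing_commute_fraction = 0)
  coh <- simulate_cohort(cfg)
  expo <- compute_cohort_exposures(coh$participants, coh$activity, coh$field,
                                   infiltration_table(), windows = 730,
                                   pollutants = c("pm25", "pm10"))
  iqr <- exposure_iqr(expo)
  for (pol in c("pm25", "pm10")) {
    v <- expo$value[expo$pollutant == pol]
    expect_equal(iqr$iqr[iqr$pollutant == pol], IQR(v))
    expect_true(all(v >= min(v) & v <= max(v)))
  }
  wide <- exposure_wide(expo)
  expect_named(wide, c("id", "pm25_730", "pm10_730"))
})

test_that("infiltration table JSON round-trips and applies the bus rule", {
  ift <- infiltration_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_infiltration_json(ift, path)
  ift2 <- read_infiltration_json(path)
  expect_equal(ift2$if_home, ift$if_home)
  expect_equal(ift2$if_transit, ift$if_transit)
  # the bus PM10 substitution survives the round trip
  expect_equal(ift2$if_transit["bus", "pm10"], ift$if_transit["bus", "pm25"])
})
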