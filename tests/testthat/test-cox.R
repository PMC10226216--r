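test_that("quartile categorization splits at the empirical quartiles", {
  qc <- quartile_categorize(1:8)
  expect_equal(as.character(qc$groups),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_equal(qc$cutpoints, unname(quantile(1:8, c(.25, .5, .75))))

  # distinct values, n = 4k -> equal group sizes
  set.seed(2)
  x <- sample(seq(0, 1, length.out = 200))
  expect_true(all(table(quartile_categorize(x)$groups) == 50))

  # a value equal to a cutpoint goes to the lower group
  xq <- c(1, 2, 3, 4, 5, 6, 7, 8)
  cut2 <- quantile(xq, 0.5)
  g <- quartile_categorize(xq)$groups
  expect_equal(as.character(g[xq == floor(cut2)]), "Q2")

  expect_error(quartile_categorize(rep(3, 10)), "distinct")
  expect_error(quartile_categorize(c(rep(1, 5), 2, 3, 4, 5, 6, 7, 8)),
               "tied")
})

test_that("per-IQR hazard ratio is exactly exp(coefficient)", {
  set.seed(41)
  d <- sim_survival_data(400, 0.05)
  f <- fit_cox(d, "exposure", model = 1, form = "iqr")
  e <- exposure_hr(f)
  expect_equal(e$hr, exp(e$estimate), tolerance = 1e-12)
  expect_true(e$lo < e$hr && e$hr < e$hi)
  # scaling by the IQR: per-IQR coefficient = per-unit coefficient * IQR
  fu <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                          exposure + age + sex, data = d, ties = "efron")
  expect_equal(e$estimate, unname(coef(fu)[1]) * IQR(d$exposure),
               tolerance = 1e-8)
})

test_that("coef/vcov/confint/predict methods delegate to the fit", {
  set.seed(42)
  d <- sim_survival_data(300, 0.05)
  f <- fit_cox(d, "exposure", model = 1)
  expect_named(coef(f), c(".exposure", "age", "sexmale"))
  expect_equal(dim(vcov(f)), c(3, 3))
  ci <- confint(f)
  expect_equal(nrow(ci), 3)
  expect_length(predict(f, type = "lp"), 300)
  expect_length(residuals(f, type = "martingale"), 300)
})

test_that("duplicating the dataset leaves point estimates unchanged", {
  set.seed(43)
  d <- sim_survival_data(250, 0.08)
  f1 <- fit_cox(d, "exposure", model = 1, form = "iqr")
  f2 <- suppressWarnings(fit_cox(rbind(d, d), "exposure", model = 1,
                                 form = "iqr", iqr = f1$iqr))
  # Efron's tie correction makes the invariance approximate (the duplicated
  # events become ties); Breslow ties give it exactly, checked below
  expect_equal(exposure_hr(f1)$estimate, exposure_hr(f2)$estimate,
               tolerance = 5e-3)
  b1 <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                          exposure + age + sex, d, ties = "breslow")
  b2 <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                          exposure + age + sex, rbind(d, d),
                        ties = "breslow")
  expect_equal(coef(b1), coef(b2), tolerance = 1e-7)
})

test_that("partial likelihood and score match the brute-force oracle", {
  set.seed(44)
  d <- sim_survival_data(200, 0.06, fu_days = 200)  # day ties guaranteed
  d$male <- as.numeric(d$sex == "male")
  X <- as.matrix(d[, c("exposure", "age", "male")])
  fit <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                           exposure + age + male, data = d, ties = "efron")
  bhat <- coef(fit)
  expect_equal(efron_loglik(bhat, X, d$follow_days, d$event_flag),
               fit$loglik[2], tolerance = 1e-8)
  # the score vanishes at the fitted maximum
  expect_lt(max(abs(efron_score(bhat, X, d$follow_days, d$event_flag))),
            1e-4)
  # and the likelihood agrees away from the maximum too
  b0 <- bhat * 0.5
  fit0 <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                            exposure + age + male, data = d, ties = "efron",
                          init = b0, control =
                            survival::coxph.control(iter.max = 0))
  expect_equal(efron_loglik(b0, X, d$follow_days, d$event_flag),
               fit0$loglik[2], tolerance = 1e-8)
})

test_that("quartile model orders hazard ratios under a monotone truth", {
  set.seed(45)
  hits <- 0
  for (r in 1:20) {
    d <- sim_survival_data(1200, 0.12, exposure_sd = 5)
    f <- fit_cox(d, "exposure", model = 1, form = "quartile")
    e <- exposure_hr(f)
    expect_equal(e$term, c("Q2", "Q3", "Q4"))
    if (!is.unsorted(e$estimate)) hits <- hits + 1
  }
  expect_gte(hits, 16)   # monotone in >= 80% of replicates
})

test_that("missing covariates and unknown columns are refused", {
  set.seed(46)
  d <- sim_survival_data(100, 0)
  d$age[3] <- NA
  expect_error(fit_cox(d, "exposure", model = 1), "missing values")
  expect_error(fit_cox(sim_survival_data(50, 0), "pm25_730", model = 1),
               "lacks column")
})

test_that("subgroup analysis partitions the cohort and flags small strata", {
  set.seed(47)
  d <- add_model3_covariates(sim_survival_data(600, 0.05))
  d$hyperuricemia <- d$ua >= ifelse(d$sex == "male", 420, 360)
  sg <- suppressMessages(subgroup_analysis(d, "exposure"))
  # each factor's strata partition the cohort
  for (fac in unique(sg$factor)) {
    expect_equal(sum(sg$n[sg$factor == fac]), 600)
  }
  # a homogeneous truth gives mutually consistent strata (overlapping CIs)
  ok <- subset(sg, !is.na(hr) & factor == "sex")
  if (nrow(ok) == 2) expect_true(ok$lo[1] <= ok$hi[2] && ok$lo[2] <= ok$hi[1])

  # tiny stratum is skipped with a note
  d2 <- d; d2$age <- pmin(d2$age, 59)
  d2$age[1:5] <- 61
  sg2 <- suppressMessages(subgroup_analysis(d2, "exposure"))
  row <- subset(sg2, factor == "age60" & stratum == ">=60")
  expect_true(is.na(row$hr))
  expect_match(row$note, "skipped")
})
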