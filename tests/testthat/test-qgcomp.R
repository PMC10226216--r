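test_that("quantization assigns left-closed quantile bins", {
  expect_equal(quantize(1:8, 4), c(0, 0, 1, 1, 2, 2, 3, 3))
  # rank invariance under monotone transforms
  set.seed(61)
  x <- rnorm(500)
  expect_identical(quantize(x, 4), quantize(exp(x), 4))
  expect_identical(quantize(x, 4), quantize(2 * x + 7, 4))
  # the maximum lands in the top bin
  expect_equal(max(quantize(x, 4)), 3)
  expect_error(quantize(rep(1, 10), 4), "degenerate")
})

test_that("uniform draws fill the quantile bins evenly", {
  set.seed(62)
  s <- quantize(runif(1000), 4)
  tab <- table(s)
  # binomial 3-sigma bound around 250
  expect_true(all(abs(tab - 250) < 3 * sqrt(1000 * 0.25 * 0.75)))
})

sim_mixture_data <- function(n, beta = rep(0.05, 6), fu = 730,
                             base_haz = 5e-4) {
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  S <- apply(X, 2, quantize, q = 4)
  lp <- drop(S %*% beta)
  t_event <- rexp(n, base_haz * exp(lp - mean(lp)))
  d <- data.frame(X, follow_days = ceiling(pmin(t_event, fu)),
                  event_flag = as.integer(t_event <= fu),
                  age = round(runif(n, 30, 70)),
                  sex = sample(c("male", "female"), n, TRUE))
  d
}

test_that("psi is exactly the sum of quantized-exposure coefficients", {
  set.seed(63)
  d <- sim_mixture_data(800)
  f <- fit_qgcomp_cox(d, paste0("x", 1:6), model = c("age", "sex"))
  expect_equal(f$psi, sum(f$coefficients), tolerance = 1e-15)
  expect_equal(f$hr, exp(f$psi), tolerance = 1e-12)
  # delta-method variance = 1' Sigma 1
  Sigma <- vcov(f$fit)[paste0("x", 1:6), paste0("x", 1:6)]
  expect_equal(f$se, sqrt(sum(Sigma)), tolerance = 1e-12)
})

test_that("sign-partitioned weights are normalised within partitions", {
  set.seed(64)
  d <- sim_mixture_data(900, beta = c(0.1, 0.08, 0.05, -0.06, 0, 0.02))
  f <- fit_qgcomp_cox(d, paste0("x", 1:6), model = c("age", "sex"))
  w <- f$weights
  pos <- w$partition == "positive"
  expect_true(all(w$weight[pos] >= 0))
  expect_equal(sum(w$weight[pos]), 1, tolerance = 1e-12)
  if (any(!pos)) {
    expect_true(all(w$weight[!pos] >= 0))
    expect_equal(sum(w$weight[!pos]), 1, tolerance = 1e-12)
  }
  # every pollutant sits in exactly one partition
  expect_equal(nrow(w), 6)
})

test_that("single-exposure mixture reduces to that exposure's coefficient", {
  set.seed(65)
  d <- sim_mixture_data(600)
  f1 <- fit_qgcomp_cox(d, "x1", model = c("age", "sex"))
  ref <- survival::coxph(survival::Surv(follow_days, event_flag) ~
                           quantize(x1, 4) + age + sex, data = d,
                         ties = "efron")
  expect_equal(f1$psi, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(f1$weights$weight, 1)
})

test_that("mixture arithmetic follows the definition for fixed coefficients", {
  # two pollutants with coefficients 0.2 and -0.05: psi = 0.15,
  # HR = exp(0.15); each partition carries a single unit weight
  b <- c(a = 0.2, b = -0.05)
  psi <- sum(b)
  expect_equal(psi, 0.15)
  expect_equal(exp(psi), 1.1618, tolerance = 1e-4)
  pos <- b >= 0
  wpos <- b[pos] / sum(b[pos]); wneg <- b[!pos] / sum(b[!pos])
  expect_equal(unname(wpos), 1)
  expect_equal(unname(wneg), 1)
})

test_that("the fitted contrast equals a brute-force g-computation oracle", {
  set.seed(66)
  d <- sim_mixture_data(400)
  exps <- paste0("x", 1:6)
  f <- fit_qgcomp_cox(d, exps, model = c("age", "sex"))
  # brute force: average predicted log-hazard with every quantized exposure
  # raised by one, minus the average at the observed scores
  qd <- d
  for (e in exps) qd[[e]] <- quantize(d[[e]], 4)
  qd1 <- qd
  for (e in exps) qd1[[e]] <- qd1[[e]] + 1
  lp0 <- predict(f$fit, newdata = qd, type = "lp")
  lp1 <- predict(f$fit, newdata = qd1, type = "lp")
  expect_equal(mean(lp1) - mean(lp0), f$psi, tolerance = 1e-10)
})

test_that("near-duplicate exposures are rejected by the collinearity screen", {
  set.seed(67)
  d <- sim_mixture_data(300)
  d$x2 <- d$x1 + rnorm(300, sd = 1e-8)
  expect_error(fit_qgcomp_cox(d, paste0("x", 1:6), model = c("age", "sex")),
               "collinearity")
})

test_that("two-pollutant models respect the correlation screen", {
  set.seed(68)
  d <- add_model3_covariates(sim_survival_data(500, 0.05))
  d$co_indep <- rnorm(500)
  d$co_high <- d$exposure + rnorm(500, sd = 0.5)   # |rho| > 0.6
  d$co_dup <- d$exposure                           # rho = 1
  res <- suppressMessages(suppressWarnings(
    two_pollutant_models(d, "exposure", c("co_indep", "co_high", "co_dup"))))
  expect_equal(res$fitted, c(TRUE, FALSE, FALSE))
  expect_match(res$note[2], "collinearity")
  expect_match(res$note[3], "collinearity")
  expect_true(is.na(res$hr[3]))

  # an independent co-pollutant leaves the index HR essentially unchanged
  f0 <- suppressWarnings(fit_cox(d, "exposure", model = 3, form = "iqr"))
  expect_lt(abs(res$hr[1] - exposure_hr(f0)$hr), 0.05)

  # all screened out -> zero fitted models
  res2 <- suppressMessages(
    two_pollutant_models(d, "exposure", c("co_high", "co_dup")))
  expect_false(any(res2$fitted))
})
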