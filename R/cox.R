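#' Covariate sets for the nested Cox models
#'
#' Model 1 adjusts for age and sex; Model 2 additionally for education,
#' smoking, drinking, physical activity intensity, excessive salt intake and
#' medication histories of hypertension, diabetes and dyslipidemia; Model 3
#' further for BMI, mean arterial pressure, fasting blood glucose, uric acid,
#' LDL-C, HDL-C and triglycerides. The "stepwise" sequence is this fixed
#' nesting, not automated variable selection.
#'
#' @param model 1, 2 or 3.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model = 3L) {
  m1 <- c("age", "sex")
  m2 <- c(m1, "education", "smoker", "drinker", "activity_intensity",
          "excess_salt", "med_hypertension", "med_diabetes",
          "med_dyslipidemia")
  m3 <- c(m2, "bmi", "map", "fbg", "ua", "ldl", "hdl", "tg")
  switch(as.character(model), "1" = m1, "2" = m2, "3" = m3,
         stop("model must be 1, 2 or 3"))
}

#' Categorize an exposure into quartile groups
#'
#' Cutpoints are the empirical 25th, 50th and 75th percentiles; values equal
#' to a cutpoint are assigned to the lower group, and Q1 is the reference
#' level in downstream models.
#'
#' @param x Numeric exposure vector with at least 4 distinct values.
#' @return List with `groups` (factor Q1-Q4) and `cutpoints` (length 3).
#' @examples
#' quartile_categorize(1:8)$groups   # Q1 Q1 Q2 Q2 Q3 Q3 Q4 Q4
#' @export
quartile_categorize <- function(x) {
  if (length(unique(x)) < 4L)
    stop("quartile categorization needs >= 4 distinct values")
  cut_at <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  breaks <- c(min(x), cut_at, max(x))
  if (anyDuplicated(breaks))
    stop("tied quartile cutpoints leave an empty group: ",
         paste(round(breaks[duplicated(breaks)], 6), collapse = ", "))
  groups <- cut(x, breaks = breaks, labels = paste0("Q", 1:4),
                right = TRUE, include.lowest = TRUE)
  if (any(table(groups) == 0L)) stop("empty quartile group")
  list(groups = groups, cutpoints = cut_at)
}

#' Fit a Cox proportional-hazards model for a time-weighted exposure
#'
#' Fits `Surv(follow_days, event_flag) ~ exposure + covariates` with Efron
#' tie handling, where the exposure enters either continuously scaled by its
#' interquartile range (hazard ratio per IQR increase) or as quartile groups
#' with Q1 as reference. Confidence intervals are Wald at the 95% level.
#'
#' @param data Data frame containing `follow_days`, `event_flag`, the
#'   exposure column and the model covariates (see [model_covariates()]).
#' @param exposure Name of the exposure column.
#' @param model Covariate set 1, 2 or 3 (default 3), or a character vector of
#'   covariate names.
#' @param form `"iqr"` (continuous, per-IQR) or `"quartile"`.
#' @param iqr IQR used for scaling; default the exposure's empirical IQR in
#'   `data`. Ignored for `form = "quartile"`.
#' @return Object of class `tw_cox`: the underlying `coxph` fit plus an
#'   `hr` table (term, estimate = log-HR, se, hr, lo, hi, p), `n`, `nevent`,
#'   `iqr`, `cutpoints`, `loglik`.
#' @export
fit_cox <- function(data, exposure, model = 3L, form = c("iqr", "quartile"),
                    iqr = NULL) {
  form <- match.arg(form)
  covars <- if (is.character(model)) model else model_covariates(model)
  .check_cox_data(data, c(exposure, covars))
  # constant covariates (e.g. medication flags within a medication-free
  # subset) carry no information and would alias the fit; drop them
  constant <- vapply(covars, function(v)
    length(unique(data[[v]])) < 2L, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covars[constant], collapse = ", "))
    covars <- covars[!constant]
  }

  cutpoints <- NULL
  if (form == "iqr") {
    if (is.null(iqr)) iqr <- stats::IQR(data[[exposure]])
    if (iqr <= 0) stop("exposure IQR must be positive")
    data$.exposure <- data[[exposure]] / iqr
    exposure_terms <- ".exposure"
  } else {
    qc <- quartile_categorize(data[[exposure]])
    data$.exposure <- qc$groups
    cutpoints <- qc$cutpoints
    exposure_terms <- ".exposure"
    iqr <- NA_real_
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(follow_days, event_flag) ~",
    paste(c(exposure_terms, covars), collapse = " + ")))
  environment(fml) <- environment()
  fit <- survival::coxph(fml, data = data, ties = "efron", x = FALSE,
                         model = FALSE)
  if (any(is.na(stats::coef(fit))))
    stop("fit error: singular model matrix (aliased coefficients)")
  npar <- length(stats::coef(fit))
  nev <- fit$nevent
  if (nev < 10 * npar)
    warning("only ", nev, " events for ", npar,
            " parameters (< 10 per parameter)")

  hr <- .wald_table(fit)
  keep <- grepl("^\\.exposure", hr$term)
  hr$term[keep] <- sub("^\\.exposure", if (form == "iqr") "per_iqr" else "",
                       hr$term[keep])
  structure(list(fit = fit, exposure = exposure, form = form, iqr = iqr,
                 cutpoints = cutpoints, hr = hr, n = fit$n, nevent = nev,
                 loglik = fit$loglik, covariates = covars),
            class = "tw_cox")
}

.check_cox_data <- function(data, cols) {
  need <- c("follow_days", "event_flag", cols)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  has_na <- vapply(data[need], anyNA, logical(1))
  if (any(has_na))
    stop("missing values in: ", paste(need[has_na], collapse = ", "),
         " (impute first)")
  invisible(TRUE)
}

.wald_table <- function(fit, level = 0.95) {
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             hr = exp(unname(b)), lo = exp(unname(b - z * se)),
             hi = exp(unname(b + z * se)),
             p = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
             row.names = NULL)
}

#' @export
print.tw_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model (%s), exposure '%s' [%s], n = %d, events = %d\n",
              paste(length(x$covariates), "covariates"), x$exposure, x$form,
              x$n, x$nevent))
  if (x$form == "iqr") cat(sprintf("  IQR used for scaling: %.4g\n", x$iqr))
  tab <- x$hr[grepl(if (x$form == "iqr") "^per_iqr" else "^Q", x$hr$term), ]
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tw_cox <- function(object, ...) {
  out <- list(hr = object$hr, n = object$n, nevent = object$nevent,
              iqr = object$iqr, cutpoints = object$cutpoints,
              loglik = object$loglik, exposure = object$exposure,
              form = object$form)
  class(out) <- "summary.tw_cox"
  out
}

#' @export
print.summary.tw_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox fit for '%s' (%s form): n = %d, events = %d\n",
              x$exposure, x$form, x$n, x$nevent))
  tab <- x$hr
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tw_cox <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.tw_cox <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.tw_cox <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$fit, parm = parm, level = level, ...)
}

#' @export
predict.tw_cox <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.tw_cox <- function(object, ...) stats::residuals(object$fit, ...)

#' Exposure hazard-ratio row(s) of a fitted Cox model
#'
#' @param x A `tw_cox`.
#' @return The rows of the HR table belonging to the exposure term(s).
#' @export
exposure_hr <- function(x) {
  stopifnot(inherits(x, "tw_cox"))
  pat <- if (x$form == "iqr") "^per_iqr" else "^Q"
  x$hr[grepl(pat, x$hr$term), , drop = FALSE]
}

#' Subgroup Cox analyses
#'
#' Refits the Model-3 per-IQR association within strata defined by the
#' standard cutpoints: sex, age 60 y, LDL-C 3.4 mmol/L, TG 1.7 mmol/L,
#' HDL-C 1.0 mmol/L, BMI 24 kg/m2 and hyperuricemia. The stratifying
#' variable (and derived collinear covariates) is removed from the
#' adjustment set within its own strata. Strata below `min_n` participants
#' or with no events are skipped with a logged reason.
#'
#' @param data Analysis data frame (see [fit_cox()]).
#' @param exposure Exposure column name.
#' @param iqr IQR for scaling (default: cohort-wide IQR in `data`, so
#'   subgroup HRs are on a common scale).
#' @param min_n Minimum stratum size (default 50).
#' @param factors Optional named list of stratum definitions
#'   (`list(label = logical vector)`); default the seven standard ones.
#' @return Data frame: factor, stratum, n, nevent, hr, lo, hi, p (NA rows
#'   carry the skip reason in `note`).
#' @export
subgroup_analysis <- function(data, exposure, iqr = NULL, min_n = 50L,
                              factors = NULL) {
  if (is.null(iqr)) iqr <- stats::IQR(data[[exposure]])
  if (is.null(factors)) {
    factors <- list(
      sex = list(male = data$sex == "male", female = data$sex == "female",
                 drop = "sex"),
      age60 = list(`>=60` = data$age >= 60, `<60` = data$age < 60,
                   drop = "age"),
      ldl = list(`>=3.4` = data$ldl >= 3.4, `<3.4` = data$ldl < 3.4,
                 drop = "ldl"),
      tg = list(`>=1.7` = data$tg >= 1.7, `<1.7` = data$tg < 1.7,
                drop = "tg"),
      hdl = list(`>=1.0` = data$hdl >= 1.0, `<1.0` = data$hdl < 1.0,
                 drop = "hdl"),
      bmi24 = list(`>=24` = data$bmi >= 24, `<24` = data$bmi < 24,
                   drop = "bmi"),
      hyperuricemia = list(yes = data$hyperuricemia,
                           no = !data$hyperuricemia, drop = "ua"))
  }
  rows <- list()
  for (fac in names(factors)) {
    spec <- factors[[fac]]
    drop_cov <- if (!is.null(spec$drop)) spec$drop else character(0)
    strata <- spec[setdiff(names(spec), "drop")]
    for (st in names(strata)) {
      sel <- strata[[st]]
      sub <- data[sel, , drop = FALSE]
      covars <- setdiff(model_covariates(3L), drop_cov)
      row <- data.frame(factor = fac, stratum = st, n = nrow(sub),
                        nevent = sum(sub$event_flag), hr = NA_real_,
                        lo = NA_real_, hi = NA_real_, p = NA_real_,
                        note = "")
      if (nrow(sub) < min_n || sum(sub$event_flag) == 0) {
        row$note <- "skipped: stratum too small or no events"
        message("subgroup ", fac, "=", st, " ", row$note)
      } else {
        f <- tryCatch(
          suppressWarnings(fit_cox(sub, exposure, model = covars,
                                   form = "iqr", iqr = iqr)),
          error = function(e) NULL)
        if (is.null(f)) {
          row$note <- "skipped: fit failed"
        } else {
          e <- exposure_hr(f)
          row$hr <- e$hr; row$lo <- e$lo; row$hi <- e$hi; row$p <- e$p
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
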