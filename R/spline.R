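#' Harrell default knot placement quantiles
#'
#' Equally spread quantiles used to place restricted-cubic-spline knots for
#' each candidate knot count.
#'
#' @param k Number of knots, 3 to 7.
#' @return Numeric vector of `k` quantile probabilities.
#' @export
rcs_knot_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
         "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
         stop("knot count must be between 3 and 7"))
}

.rcs_basis <- function(x, knots) {
  # natural cubic spline space with the outer knots as boundary knots:
  # linear beyond the boundaries, df = length(knots) - 1
  k <- length(knots)
  splines::ns(x, knots = knots[-c(1, k)], Boundary.knots = knots[c(1, k)])
}

#' Restricted-cubic-spline exposure-response curve from a Cox model
#'
#' Fits `Surv ~ rcs(exposure) + covariates` for candidate knot counts 3-7
#' (knots at the Harrell default quantiles of the exposure, natural cubic
#' spline basis: linear beyond the boundary knots) and selects the count
#' minimising the AIC of the partial likelihood. A spline with `k` knots has
#' `k - 1` degrees of freedom, so the conventional 3-df display curve is the
#' 4-knot fit, always reported alongside the AIC winner. The hazard-ratio
#' curve is normalised to HR = 1 at the reference exposure (the median by
#' default), with pointwise Wald confidence bands from the covariance of the
#' spline coefficients. A Wald-free likelihood-ratio test against the linear
#' model quantifies departure from linearity.
#'
#' @inheritParams fit_cox
#' @param knots Either `NULL` (AIC selection over 3-7) or a fixed knot count.
#' @param ref Reference exposure value (default: median of `data[[exposure]]`).
#' @param grid_n Length of the prediction grid (default 100).
#' @return Object of class `tw_rcs`: `knots` (locations of the selected fit),
#'   `n_knots`, `aic` (candidate table), `fit` (selected `coxph`),
#'   `fit_3df` (the 4-knot fit), `curve` (grid data frame: exposure, hr, lo,
#'   hi), `ref`, `linearity_p` (LRT p-value, selected fit vs linear),
#'   `exposure`.
#' @export
fit_spline <- function(data, exposure, model = 3L, knots = NULL,
                       ref = NULL, grid_n = 100L) {
  covars <- if (is.character(model)) model else model_covariates(model)
  .check_cox_data(data, c(exposure, covars))
  x <- data[[exposure]]
  if (is.null(ref)) ref <- stats::median(x)

  candidates <- if (is.null(knots)) 3:7 else as.integer(knots)
  if (any(candidates < 3L | candidates > 7L))
    stop("knot counts must lie in [3, 7]")

  fit_k <- function(k) {
    kq <- stats::quantile(x, rcs_knot_quantiles(k), names = FALSE)
    if (anyDuplicated(kq))
      stop("fewer distinct exposure values than knots (k = ", k, ")")
    basis <- .rcs_basis(x, kq)
    dd <- data
    dd$.basis <- basis
    fml <- stats::as.formula(paste(
      "survival::Surv(follow_days, event_flag) ~ .basis +",
      paste(covars, collapse = " + ")))
    environment(fml) <- environment()
    fit <- survival::coxph(fml, data = dd, ties = "efron")
    list(k = k, knots = kq, fit = fit, aic = stats::AIC(fit))
  }

  fits <- lapply(candidates, fit_k)
  aic_tab <- data.frame(knots = vapply(fits, `[[`, 0L, "k"),
                        df = vapply(fits, `[[`, 0L, "k") - 1L,
                        aic = vapply(fits, `[[`, 0, "aic"))
  best <- fits[[which.min(aic_tab$aic)]]
  fit_3df <- if (any(aic_tab$knots == 4L))
    fits[[which(aic_tab$knots == 4L)]] else fit_k(4L)

  # linear comparison model for the departure-from-linearity LRT
  dd <- data
  dd$.lin <- x
  fml_lin <- stats::as.formula(paste(
    "survival::Surv(follow_days, event_flag) ~ .lin +",
    paste(covars, collapse = " + ")))
  environment(fml_lin) <- environment()
  fit_lin <- survival::coxph(fml_lin, data = dd, ties = "efron")
  df_diff <- (best$k - 1L) - 1L
  lrt <- 2 * (best$fit$loglik[2] - fit_lin$loglik[2])
  linearity_p <- stats::pchisq(max(lrt, 0), df_diff, lower.tail = FALSE)

  curve <- .rcs_curve(best, x, ref, grid_n)
  structure(list(knots = best$knots, n_knots = best$k, aic = aic_tab,
                 fit = best$fit, fit_3df = fit_3df$fit,
                 knots_3df = fit_3df$knots, curve = curve, ref = ref,
                 linearity_p = linearity_p, exposure = exposure,
                 covariates = covars),
            class = "tw_rcs")
}

.rcs_curve <- function(fitrec, x, ref, grid_n, level = 0.95) {
  grid <- seq(stats::quantile(x, 0.01), stats::quantile(x, 0.99),
              length.out = grid_n)
  B <- .rcs_basis(c(ref, grid), fitrec$knots)
  Bref <- B[1, , drop = FALSE]
  Bg <- B[-1, , drop = FALSE]
  idx <- grep("^\\.basis", names(stats::coef(fitrec$fit)))
  beta <- stats::coef(fitrec$fit)[idx]
  Sigma <- stats::vcov(fitrec$fit)[idx, idx, drop = FALSE]
  D <- sweep(Bg, 2, Bref, `-`)            # contrast vs reference
  lp <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% Sigma) * D))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(exposure = grid, hr = exp(lp), lo = exp(lp - z * se),
             hi = exp(lp + z * se))
}

#' @export
print.tw_rcs <- function(x, ...) {
  cat(sprintf(
    "Restricted cubic spline exposure-response for '%s'\n", x$exposure))
  cat(sprintf("  selected %d knots (df = %d) by AIC; reference = %.4g (HR = 1)\n",
              x$n_knots, x$n_knots - 1L, x$ref))
  cat(sprintf("  departure-from-linearity LRT p = %.3g\n", x$linearity_p))
  print(x$aic, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tw_rcs <- function(object, ...) {
  structure(list(n_knots = object$n_knots, knots = object$knots,
                 aic = object$aic, ref = object$ref,
                 linearity_p = object$linearity_p,
                 exposure = object$exposure), class = "summary.tw_rcs")
}

#' @export
print.summary.tw_rcs <- function(x, ...) {
  cat(sprintf("RCS fit for '%s': %d knots at %s\n", x$exposure, x$n_knots,
              paste(round(x$knots, 3), collapse = ", ")))
  cat(sprintf("  reference %.4g, linearity p = %.3g\n", x$ref, x$linearity_p))
  invisible(x)
}

#' Predict the hazard-ratio curve at new exposure values
#'
#' @param object A `tw_rcs`.
#' @param newexposure Numeric vector of exposure values (default: the fitted
#'   grid).
#' @param ... Unused.
#' @return Data frame `exposure`, `hr`, `lo`, `hi` (HR relative to the
#'   reference).
#' @export
predict.tw_rcs <- function(object, newexposure = NULL, ...) {
  if (is.null(newexposure)) return(object$curve)
  rec <- list(knots = object$knots, fit = object$fit)
  B <- .rcs_basis(c(object$ref, newexposure), object$knots)
  idx <- grep("^\\.basis", names(stats::coef(object$fit)))
  beta <- stats::coef(object$fit)[idx]
  Sigma <- stats::vcov(object$fit)[idx, idx, drop = FALSE]
  D <- sweep(B[-1, , drop = FALSE], 2, B[1, , drop = FALSE], `-`)
  lp <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% Sigma) * D))
  z <- stats::qnorm(0.975)
  data.frame(exposure = newexposure, hr = exp(lp), lo = exp(lp - z * se),
             hi = exp(lp + z * se))
}

#' Plot an exposure-response curve
#'
#' Base-graphics plot of the hazard-ratio curve with its pointwise
#' confidence band, the HR = 1 line and knot tick marks.
#'
#' @param x A `tw_rcs`.
#' @param ... Passed to [plot()].
#' @export
plot.tw_rcs <- function(x, ...) {
  cv <- x$curve
  plot(cv$exposure, cv$hr, type = "n",
       ylim = range(cv$lo, cv$hi),
       xlab = x$exposure, ylab = "Hazard ratio", ...)
  graphics::polygon(c(cv$exposure, rev(cv$exposure)), c(cv$lo, rev(cv$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(cv$exposure, cv$hr, col = "steelblue", lwd = 2)
  graphics::abline(h = 1, lty = 2)
  graphics::rug(x$knots)
  invisible(x)
}
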