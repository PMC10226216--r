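#' Specify a synthetic daily ambient concentration field
#'
#' Stands in for a fitted land-use-regression-type concentration predictor:
#' anything honouring the [concentration_at()] contract (a deterministic daily
#' outdoor concentration at arbitrary planar coordinates) can be plugged into
#' the exposure model; this synthetic implementation is what the package ships.
#'
#' The field for pollutant *p* on day *t* at location *(x, y)* is
#' \deqn{C_p(x, y, t) = \max\{0,\; \mu_p + A_p \cos(2\pi (d_t - \phi_p)/365.25)
#'   + g_p \cdot (x, y) + \epsilon_{p,t}\}}
#' with annual mean \eqn{\mu_p}, seasonal amplitude \eqn{A_p} peaking on
#' day-of-year \eqn{\phi_p}, a linear spatial gradient \eqn{g_p} (units per
#' km), and a day-to-day noise vector \eqn{\epsilon_t} that is shared across
#' space and correlated across pollutants with the configured correlation
#' matrix. Sharing the noise across space keeps the field spatially smooth
#' (two nearby addresses differ only through the gradient) and makes lookups
#' deterministic: the noise matrix is drawn once at construction from `seed`
#' (the caller's RNG state is left untouched).
#'
#' Defaults emulate a polluted northern-hemisphere city: winter-peaking
#' particulate and combustion pollutants, summer-peaking ozone, positive
#' pairwise noise correlations except ozone (negative with the others).
#' Negative values produced by the tails are clipped at zero, mirroring the
#' removal of negative monitor readings in observational records;
#' [field_clip_fraction()] reports how often clipping occurs (well under 1%
#' under the defaults).
#'
#' @param start,end Date range covered (inclusive), as `Date` or coercible.
#' @param params Data frame with one row per pollutant and columns
#'   `pollutant`, `annual_mean`, `amplitude`, `peak_doy`, `gx`, `gy`,
#'   `noise_sd`. Defaults supplied.
#' @param corr Pollutant-by-pollutant correlation matrix of the daily noise;
#'   must be symmetric positive semi-definite with unit diagonal.
#' @param seed Integer seed for the noise draw.
#'
#' @return An object of class `ambient_field`.
#' @examples
#' fld <- field_spec("2015-01-01", "2015-12-31", seed = 1)
#' concentration_at(fld, "pm25", c(5, 5), as.Date("2015-06-01"))
#' @export
field_spec <- function(start, end, params = NULL, corr = NULL, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  seed <- as.integer(seed)
  if (end < start) stop("field coverage: end precedes start")
  if (is.null(params)) params <- default_field_params()
  if (!all(POLLUTANTS %in% params$pollutant))
    stop("params must cover every pollutant")
  params <- params[match(POLLUTANTS, params$pollutant), ]
  if (is.null(corr)) corr <- default_field_corr()
  corr <- as.matrix(corr)
  dimnames(corr) <- list(POLLUTANTS, POLLUTANTS)
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8))
    stop("corr must be symmetric with unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("corr must be positive semi-definite")

  dates <- seq(start, end, by = "day")
  noise <- .with_seed(seed, {
    z <- matrix(stats::rnorm(length(dates) * length(POLLUTANTS)),
                length(dates), length(POLLUTANTS))
    # eigen-based square root tolerates semi-definite matrices
    e <- eigen(corr, symmetric = TRUE)
    z %*% (e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors))
  })
  noise <- sweep(noise, 2, params$noise_sd, `*`)
  colnames(noise) <- POLLUTANTS

  structure(list(start = start, end = end, dates = dates,
                 params = params, corr = corr, noise = noise, seed = seed),
            class = "ambient_field")
}

# run expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default pollutant field parameters
#'
#' Annual means and seasonal amplitudes loosely follow a heavily polluted
#' city's climatology (units ug/m3, CO in mg/m3); spatial gradients are in
#' concentration units per km of planar displacement.
#'
#' @return Data frame with one row per pollutant.
#' @export
default_field_params <- function() {
  data.frame(
    pollutant   = c("pm25", "pm10", "so2", "no2", "co", "o3"),
    annual_mean = c(60,     95,     15,    45,    1.2,  55),
    amplitude   = c(22,     28,     6,     12,    0.4,  20),
    peak_doy    = c(15,     15,     15,    15,    15,   195),
    gx          = c(0.50,   0.70,   0.12,  0.35,  0.008, -0.20),
    gy          = c(0.30,   0.45,   0.08,  0.20,  0.005, -0.12),
    noise_sd    = c(18,     24,     4,     11,    0.30, 10)
  )
}

#' Default cross-pollutant noise correlation
#'
#' Positive among the combustion-related pollutants, negative between ozone
#' and the rest (titration against fresh NO emissions).
#'
#' @return 6x6 correlation matrix.
#' @export
default_field_corr <- function() {
  m <- matrix(c(
    1.00, 0.85, 0.55, 0.60, 0.65, -0.25,
    0.85, 1.00, 0.55, 0.55, 0.55, -0.20,
    0.55, 0.55, 1.00, 0.50, 0.55, -0.30,
    0.60, 0.55, 0.50, 1.00, 0.60, -0.40,
    0.65, 0.55, 0.55, 0.60, 1.00, -0.30,
    -0.25, -0.20, -0.30, -0.40, -0.30, 1.00), 6, 6)
  dimnames(m) <- list(POLLUTANTS, POLLUTANTS)
  m
}

.field_day_index <- function(field, dates) {
  dates <- as.Date(dates)
  idx <- as.integer(dates - field$start) + 1L
  if (any(idx < 1L | idx > length(field$dates)))
    stop("date outside field coverage (", field$start, " .. ", field$end, ")")
  idx
}

# city-wide daily series (mean + seasonal + noise) for one pollutant; no
# spatial term, no clipping
.field_series <- function(field, pollutant) {
  p <- match(pollutant, POLLUTANTS)
  if (is.na(p)) stop("unknown pollutant: ", pollutant)
  pr <- field$params[p, ]
  doy <- as.integer(format(field$dates, "%j"))
  pr$annual_mean + pr$amplitude * cos(2 * pi * (doy - pr$peak_doy) / 365.25) +
    field$noise[, p]
}

#' Look up a daily outdoor concentration
#'
#' Deterministic given the field object: repeated calls with the same
#' arguments return identical values.
#'
#' @param field An [field_spec()] object (or any object providing a
#'   `concentration_at` method honouring this contract).
#' @param pollutant One of [POLLUTANTS].
#' @param xy Numeric length-2 planar coordinates (km).
#' @param dates Vector of dates within the field's coverage.
#' @return Numeric vector of non-negative concentrations, one per date.
#' @export
concentration_at <- function(field, pollutant, xy, dates) {
  UseMethod("concentration_at")
}

#' @export
concentration_at.ambient_field <- function(field, pollutant, xy, dates) {
  idx <- .field_day_index(field, dates)
  p <- match(pollutant, POLLUTANTS)
  if (is.na(p)) stop("unknown pollutant: ", pollutant)
  pr <- field$params[p, ]
  series <- .field_series(field, pollutant)
  pmax(0, series[idx] + pr$gx * xy[1] + pr$gy * xy[2])
}

#' Fraction of days clipped to zero at a location
#'
#' @inheritParams concentration_at
#' @return Proportion of days in the field's coverage on which the raw value
#'   was negative before clipping.
#' @export
field_clip_fraction <- function(field, pollutant, xy = c(0, 0)) {
  p <- match(pollutant, POLLUTANTS)
  if (is.na(p)) stop("unknown pollutant: ", pollutant)
  pr <- field$params[p, ]
  raw <- .field_series(field, pollutant) + pr$gx * xy[1] + pr$gy * xy[2]
  mean(raw < 0)
}

#' @export
print.ambient_field <- function(x, ...) {
  cat("Synthetic ambient concentration field:",
      format(x$start), "..", format(x$end),
      sprintf("(%d days, seed %d)\n", length(x$dates), x$seed))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation matrix between exposure series
#'
#' Rank correlations between aligned series (e.g. individual time-weighted
#' exposures to each pollutant). A constant series has no defined rank
#' correlation; the corresponding entries are set to `NA` with a warning
#' rather than silently reported as zero.
#'
#' @param x Numeric matrix or data frame, one column per series, equal-length
#'   aligned rows.
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   constant series are `NA`.
#' @examples
#' spearman_matrix(cbind(a = 1:4, b = c(1, 3, 2, 4)))  # off-diagonal 0.8
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  const <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  if (any(const)) {
    warning("constant series: correlation undefined for ",
            paste(colnames(x)[const], collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- ifelse(const, NA_real_, 1)
  rho
}

#' Write / read an ambient field as a long-format CSV
#'
#' One row per (pollutant, location, date). `read_ambient_csv()` returns the
#' plain data frame; it is a data exchange format, not a reconstruction of the
#' generating `ambient_field` object.
#'
#' @param field An `ambient_field`.
#' @param locations Data frame with columns `location_id`, `x`, `y`.
#' @param path File path.
#' @return `write_ambient_csv()` returns `path` invisibly;
#'   `read_ambient_csv()` a data frame with columns `pollutant`,
#'   `location_id`, `x`, `y`, `date`, `value`.
#' @export
write_ambient_csv <- function(field, locations, path) {
  stopifnot(all(c("location_id", "x", "y") %in% names(locations)))
  out <- do.call(rbind, lapply(seq_len(nrow(locations)), function(i) {
    loc <- locations[i, ]
    do.call(rbind, lapply(POLLUTANTS, function(p) {
      data.frame(pollutant = p, location_id = loc$location_id,
                 x = loc$x, y = loc$y, date = field$dates,
                 value = concentration_at(field, p, c(loc$x, loc$y),
                                          field$dates))
    }))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ambient_csv
#' @export
read_ambient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pollutant", "location_id", "x", "y", "date", "value")
  if (!all(need %in% names(df)))
    stop("ambient CSV must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  if (any(df$value < 0)) stop("ambient CSV contains negative concentrations")
  df
}

#' Read / write a field specification as JSON
#'
#' Serialises the generating configuration (dates, per-pollutant parameters,
#' correlation matrix, seed); the field is reconstructed deterministically
#' from it, so a round trip reproduces identical concentrations.
#'
#' @param field An `ambient_field`.
#' @param path File path.
#' @return `write_field_spec_json()` returns `path` invisibly;
#'   `read_field_spec_json()` a reconstructed `ambient_field`.
#' @export
write_field_spec_json <- function(field, path) {
  stopifnot(inherits(field, "ambient_field"))
  obj <- list(start = format(field$start), end = format(field$end),
              params = field$params, corr = as.data.frame(field$corr),
              seed = field$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_field_spec_json
#' @export
read_field_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- obj$corr
  cc[["_row"]] <- NULL           # serialized row names
  field_spec(obj$start, obj$end, params = as.data.frame(obj$params),
             corr = as.matrix(as.data.frame(cc)), seed = obj$seed)
}
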