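#' Infiltration factor table
#'
#' Builds and validates the infiltration factors used by the exposure model:
#' `if_home`, the fraction of the outdoor concentration found indoors at home
#' or at the workplace, and `if_transit`, the in-vehicle fraction by commute
#' mode. All factors must lie in (0, 1].
#'
#' The shipped defaults are plausible mid-range values for urban Chinese
#' buildings and vehicles and are *configurable defaults*, not measured
#' constants: any user-supplied table satisfying the (0, 1] constraint is
#' accepted and all downstream results are reproducible under it. Two
#' conventions are built in: active commuting (walking/cycling) is outdoor
#' exposure, so its factor is 1 for every pollutant; and a missing PM10 bus
#' factor is substituted by the PM2.5 bus factor, reflecting the scarcity of
#' measured in-bus PM10 infiltration.
#'
#' @param if_home Named numeric vector of indoor infiltration factors, one per
#'   pollutant in [POLLUTANTS].
#' @param if_transit Numeric matrix of in-vehicle factors with rows
#'   [COMMUTE_MODES] and columns [POLLUTANTS]. An `NA` in the
#'   `("bus", "pm10")` cell is filled with the `("bus", "pm25")` value.
#'
#' @return An object of class `infiltration_table`: a list with elements
#'   `if_home` (named vector) and `if_transit` (mode x pollutant matrix).
#' @examples
#' ift <- infiltration_table()
#' ift$if_home["pm25"]
#' ift$if_transit["bus", "pm10"]  # equals the pm25 bus factor by default
#' @export
infiltration_table <- function(if_home = NULL, if_transit = NULL) {
  if (is.null(if_home)) {
    if_home <- c(pm25 = 0.70, pm10 = 0.45, so2 = 0.40,
                 no2 = 0.60, co = 0.90, o3 = 0.30)
  }
  if (is.null(if_transit)) {
    if_transit <- rbind(
      car    = c(pm25 = 0.45, pm10 = 0.35, so2 = 0.35, no2 = 0.55, co = 0.95, o3 = 0.25),
      active = c(pm25 = 1.00, pm10 = 1.00, so2 = 1.00, no2 = 1.00, co = 1.00, o3 = 1.00),
      bus    = c(pm25 = 0.65, pm10 = NA,   so2 = 0.45, no2 = 0.70, co = 0.95, o3 = 0.35),
      subway = c(pm25 = 0.40, pm10 = 0.30, so2 = 0.25, no2 = 0.40, co = 0.80, o3 = 0.15)
    )
  }
  if (!all(POLLUTANTS %in% names(if_home)))
    stop("if_home must name every pollutant: ", paste(POLLUTANTS, collapse = ", "))
  if_home <- if_home[POLLUTANTS]
  if_transit <- as.matrix(if_transit)
  if (!all(COMMUTE_MODES %in% rownames(if_transit)) ||
      !all(POLLUTANTS %in% colnames(if_transit)))
    stop("if_transit must have rows ", paste(COMMUTE_MODES, collapse = ", "),
         " and columns ", paste(POLLUTANTS, collapse = ", "))
  if_transit <- if_transit[COMMUTE_MODES, POLLUTANTS]
  # bus PM10 substitution rule
  if (is.na(if_transit["bus", "pm10"]))
    if_transit["bus", "pm10"] <- if_transit["bus", "pm25"]
  .check_if_range(if_home, "if_home")
  .check_if_range(if_transit, "if_transit")
  structure(list(if_home = if_home, if_transit = if_transit),
            class = "infiltration_table")
}

.check_if_range <- function(x, what) {
  if (anyNA(x) || any(x <= 0) || any(x > 1))
    stop(what, ": all infiltration factors must lie in (0, 1]")
  invisible(TRUE)
}

#' Unit infiltration table (no attenuation)
#'
#' Convenience constructor for the sensitivity analysis in which infiltration
#' is ignored: every factor is 1, so indoor and in-vehicle exposure equals the
#' ambient concentration.
#'
#' @return An `infiltration_table` with all factors equal to 1.
#' @export
infiltration_unit <- function() {
  ifh <- stats::setNames(rep(1, length(POLLUTANTS)), POLLUTANTS)
  ift <- matrix(1, length(COMMUTE_MODES), length(POLLUTANTS),
                dimnames = list(COMMUTE_MODES, POLLUTANTS))
  infiltration_table(if_home = ifh, if_transit = ift)
}

#' @export
print.infiltration_table <- function(x, ...) {
  cat("Infiltration factors\n  indoor (home/work):\n")
  print(round(x$if_home, 3))
  cat("  in-vehicle by commute mode:\n")
  print(round(x$if_transit, 3))
  invisible(x)
}

#' Read / write an infiltration table as JSON
#'
#' @param ift An [infiltration_table()].
#' @param path File path.
#' @return `write_infiltration_json()` returns `path` invisibly;
#'   `read_infiltration_json()` a validated `infiltration_table`.
#' @export
write_infiltration_json <- function(ift, path) {
  stopifnot(inherits(ift, "infiltration_table"))
  obj <- list(if_home = as.list(ift$if_home),
              if_transit = lapply(seq_len(nrow(ift$if_transit)), function(i)
                as.list(ift$if_transit[i, ])))
  names(obj$if_transit) <- rownames(ift$if_transit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_infiltration_json
#' @export
read_infiltration_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if_home <- unlist(obj$if_home)
  if_transit <- do.call(rbind, lapply(obj$if_transit, unlist))
  infiltration_table(if_home = if_home, if_transit = if_transit)
}
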