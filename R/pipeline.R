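#' Configuration for a full analysis run
#'
#' Bundles either a [cohort_config()] (simulation) or paths to cohort /
#' activity CSV inputs with the analysis settings: exposure windows, model
#' covariate sets, and the sensitivity-analysis toggles.
#'
#' @param cohort A [cohort_config()], or a list
#'   `list(participants = path, activity = path)` of CSV inputs paired with a
#'   `field` object.
#' @param windows Trailing windows in days (default `c(365, 730)`).
#' @param models Covariate sets to fit (default `1:3`).
#' @param pollutants Pollutants analysed individually (default PM2.5, PM10).
#' @param mixture_pollutants Pollutants entering the mixture model (default
#'   all six).
#' @param sensitivity Character vector among `"no_infiltration"`,
#'   `"medication_free"`, `"complete_case"`, `"two_pollutant"`,
#'   `"window_sweep"` (default: all).
#' @param subgroups Run the subgroup battery (default TRUE).
#' @param ift An [infiltration_table()] (default the shipped one).
#' @param m_imputations Imputations for missing commute times (default 5).
#' @param seed Seed recorded in the manifest and used for imputation.
#' @param output_dir Directory for the report bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       windows = c(365L, 730L),
                       models = 1:3,
                       pollutants = c("pm25", "pm10"),
                       mixture_pollutants = POLLUTANTS,
                       sensitivity = c("no_infiltration", "medication_free",
                                       "complete_case", "two_pollutant",
                                       "window_sweep"),
                       subgroups = TRUE,
                       ift = infiltration_table(),
                       m_imputations = 5L,
                       seed = 1L,
                       output_dir = tempfile("airtwa_run_")) {
  if (!length(windows) || !length(models))
    stop("at least one window and one model are required")
  if (length(sensitivity)) sensitivity <- match.arg(sensitivity,
                                                    several.ok = TRUE)
  else sensitivity <- character(0)
  structure(list(cohort = cohort, windows = as.integer(windows),
                 models = as.integer(models), pollutants = pollutants,
                 mixture_pollutants = mixture_pollutants,
                 sensitivity = sensitivity, subgroups = subgroups,
                 ift = ift, m_imputations = as.integer(m_imputations),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Exclusion filter mirroring the enrollment flow
#'
#' Excludes participants with a missing home or work address and those with
#' prevalent coronary heart disease, cancer or cerebrovascular disease
#' (`prevalent_disease` flag). A participant matching both reasons is counted
#' once, with both reasons listed.
#'
#' @param participants Participant data frame.
#' @return List with `included` (data frame) and `excluded` (data frame of
#'   `id`, `reasons`).
#' @export
exclusion_filter <- function(participants) {
  miss_addr <- is.na(participants$home_x) | is.na(participants$home_y) |
    is.na(participants$work_x) | is.na(participants$work_y)
  prev <- if ("prevalent_disease" %in% names(participants))
    participants$prevalent_disease else rep(FALSE, nrow(participants))
  any_excl <- miss_addr | prev
  reasons <- character(sum(any_excl))
  idx <- which(any_excl)
  reasons <- vapply(idx, function(i) {
    paste(c(if (miss_addr[i]) "missing address",
            if (prev[i]) "prevalent disease"), collapse = "; ")
  }, character(1))
  message("exclusion filter: ", nrow(participants), " assessed, ",
          sum(any_excl), " excluded (", sum(miss_addr), " missing address, ",
          sum(prev), " prevalent disease), ",
          sum(!any_excl), " enrolled")
  list(included = participants[!any_excl, , drop = FALSE],
       excluded = data.frame(id = participants$id[idx], reasons = reasons))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate/load -> exclusion filter -> commute-time imputation ->
#' time-weighted exposures -> Cox fits (per model, pollutant, window, in
#' per-IQR and quartile form) -> spline curves -> quantile g-computation ->
#' sensitivity analyses -> subgroups, writing each table to the bundle
#' directory together with a manifest (seed, config hash, counts). With
#' missing commute times the per-IQR, quartile and mixture estimates are
#' pooled over the `m` imputed datasets by Rubin's rules; the spline uses
#' the first completed dataset.
#'
#' Deterministic: identical config + seed produce byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory results (`exposures`, `fits`,
#'   `splines`, `mixture`, `sensitivity`, `subgroups`, `manifest`,
#'   `output_dir`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  # ---- stage: cohort -------------------------------------------------
  if (inherits(config$cohort, "cohort_config")) {
    cohort <- simulate_cohort(config$cohort)
    participants <- cohort$participants
    activity <- cohort$activity
    field <- cohort$field
  } else {
    participants <- utils::read.csv(config$cohort$participants,
                                    stringsAsFactors = FALSE)
    participants$index_date <- as.Date(participants$index_date)
    activity <- utils::read.csv(config$cohort$activity,
                                stringsAsFactors = FALSE)
    field <- config$cohort$field
    if (is.null(field)) stop("file-based cohort input needs a field object")
  }

  flt <- exclusion_filter(participants)
  participants <- flt$included
  activity <- activity[activity$id %in% participants$id, , drop = FALSE]
  utils::write.csv(flt$excluded, out("exclusions.csv"), row.names = FALSE)

  # ---- stage: imputation --------------------------------------------
  n_missing <- sum(is.na(activity$t_trans))
  imputed <- impute_missing_times(activity, m = config$m_imputations,
                                  seed = config$seed)

  # ---- stage: exposures ---------------------------------------------
  windows_all <- config$windows
  if ("window_sweep" %in% config$sensitivity) {
    max_hist <- as.integer(min(as.Date(participants$index_date)) - field$start)
    sweep_w <- c(365L, 730L, 1095L, 1460L, 1825L)
    windows_all <- sort(unique(c(windows_all, sweep_w[sweep_w <= max_hist])))
  }
  expo_m <- lapply(imputed, function(act)
    compute_cohort_exposures(participants, act, field, config$ift,
                             windows = windows_all,
                             pollutants = union(config$pollutants,
                                                config$mixture_pollutants)))
  expo <- expo_m[[1]]
  write_exposure_csv(expo, out("exposure.csv"), out("exposure_iqr.json"))
  utils::write.csv(exposure_iqr(expo), out("exposure_iqr.csv"),
                   row.names = FALSE)

  wide_m <- lapply(expo_m, function(e)
    merge(participants, exposure_wide(e), by = "id", sort = TRUE))

  # ---- stage: Cox fits ----------------------------------------------
  fits <- .fit_battery(wide_m, config$models, config$pollutants,
                       config$windows)
  utils::write.csv(fits, out("cox_fits.csv"), row.names = FALSE)

  # ---- stage: splines -----------------------------------------------
  splines_tab <- list()
  for (pol in config$pollutants) for (w in config$windows) {
    key <- paste0(pol, "_", w)
    sp <- fit_spline(wide_m[[1]], key, model = 3L)
    cv <- sp$curve
    cv$pollutant <- pol; cv$window <- w
    cv$n_knots <- sp$n_knots; cv$linearity_p <- sp$linearity_p
    splines_tab[[key]] <- sp
    utils::write.csv(cv, out(paste0("spline_", key, ".csv")),
                     row.names = FALSE)
  }

  # ---- stage: mixture -----------------------------------------------
  mixture <- list()
  mix_rows <- list()
  for (w in config$windows) {
    keys <- paste0(config$mixture_pollutants, "_", w)
    fits_w <- lapply(wide_m, function(d)
      fit_qgcomp_cox(d, keys, model = 3L))
    pooled <- pool_rubin(vapply(fits_w, `[[`, 0, "psi"),
                         vapply(fits_w, `[[`, 0, "se"))
    z <- stats::qnorm(0.975)
    mixture[[as.character(w)]] <- fits_w[[1]]
    mix_rows[[as.character(w)]] <- data.frame(
      window = w, psi = pooled$estimate, se = pooled$se,
      hr = exp(pooled$estimate),
      lo = exp(pooled$estimate - z * pooled$se),
      hi = exp(pooled$estimate + z * pooled$se))
    wdf <- fits_w[[1]]$weights
    wdf$window <- w
    utils::write.csv(wdf, out(paste0("qgcomp_weights_", w, ".csv")),
                     row.names = FALSE)
  }
  mix_tab <- do.call(rbind, mix_rows)
  utils::write.csv(mix_tab, out("qgcomp.csv"), row.names = FALSE)
  jsonlite::write_json(mix_tab, out("qgcomp.json"), dataframe = "rows",
                       digits = NA)

  # ---- stage: sensitivity -------------------------------------------
  sens <- list()
  if ("no_infiltration" %in% config$sensitivity) {
    expo_u <- compute_cohort_exposures(participants, imputed[[1]], field,
                                       infiltration_unit(),
                                       windows = config$windows,
                                       pollutants = config$pollutants)
    write_exposure_csv(expo_u, out("exposure_no_infiltration.csv"))
    wide_u <- merge(participants, exposure_wide(expo_u), by = "id",
                    sort = TRUE)
    sens$no_infiltration <- .fit_battery(list(wide_u), 3L,
                                         config$pollutants, config$windows)
    utils::write.csv(sens$no_infiltration,
                     out("sensitivity_no_infiltration.csv"),
                     row.names = FALSE)
  }
  if ("medication_free" %in% config$sensitivity) {
    sel <- !(wide_m[[1]]$med_hypertension | wide_m[[1]]$med_diabetes |
               wide_m[[1]]$med_dyslipidemia)
    sub_m <- lapply(wide_m, function(d) d[sel, , drop = FALSE])
    sens$medication_free <- .fit_battery(sub_m, 3L, config$pollutants,
                                         config$windows)
    utils::write.csv(sens$medication_free,
                     out("sensitivity_medication_free.csv"),
                     row.names = FALSE)
  }
  if ("complete_case" %in% config$sensitivity && n_missing > 0) {
    cc_ids <- activity$id[!is.na(activity$t_trans)]
    sub <- wide_m[[1]][wide_m[[1]]$id %in% cc_ids, , drop = FALSE]
    sens$complete_case <- .fit_battery(list(sub), 3L, config$pollutants,
                                       config$windows)
    utils::write.csv(sens$complete_case, out("sensitivity_complete_case.csv"),
                     row.names = FALSE)
  }
  if ("two_pollutant" %in% config$sensitivity) {
    tp <- list()
    for (pol in config$pollutants) for (w in config$windows) {
      key <- paste0(pol, "_", w)
      cos <- paste0(setdiff(config$mixture_pollutants, pol), "_", w)
      t <- two_pollutant_models(wide_m[[1]], key, cos, model = 3L)
      t$pollutant <- pol; t$window <- w
      tp[[key]] <- t
    }
    sens$two_pollutant <- do.call(rbind, tp)
    utils::write.csv(sens$two_pollutant, out("sensitivity_two_pollutant.csv"),
                     row.names = FALSE)
  }
  if ("window_sweep" %in% config$sensitivity) {
    sweep_w <- setdiff(windows_all, config$windows)
    if (length(sweep_w)) {
      sens$window_sweep <- .fit_battery(wide_m, 3L, config$pollutants,
                                        sweep_w)
      utils::write.csv(sens$window_sweep, out("sensitivity_window_sweep.csv"),
                       row.names = FALSE)
    }
  }

  # ---- stage: subgroups ---------------------------------------------
  subgroups <- NULL
  if (isTRUE(config$subgroups)) {
    sg <- list()
    for (pol in config$pollutants) for (w in config$windows) {
      key <- paste0(pol, "_", w)
      t <- suppressMessages(subgroup_analysis(wide_m[[1]], key))
      t$pollutant <- pol; t$window <- w
      sg[[key]] <- t
    }
    subgroups <- do.call(rbind, sg)
    utils::write.csv(subgroups, out("subgroups.csv"), row.names = FALSE)
  }

  # ---- manifest ------------------------------------------------------
  cfg_json <- jsonlite::toJSON(.config_digestible(config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("airtwa")),
    seed = config$seed, config_hash = unname(tools::md5sum(tf)),
    n_assessed = nrow(flt$included) + nrow(flt$excluded),
    n_excluded = nrow(flt$excluded), n_analysed = nrow(participants),
    n_events = sum(participants$event_flag),
    n_missing_commute = n_missing, m_imputations = config$m_imputations,
    windows = windows_all, models = config$models,
    pollutants = config$pollutants, sensitivity = config$sensitivity)
  unlink(tf)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(exposures = expo, fits = fits, splines = splines_tab,
                 mixture = mixture, mixture_table = mix_tab,
                 sensitivity = sens, subgroups = subgroups,
                 exclusions = flt$excluded, manifest = manifest,
                 data = wide_m[[1]], output_dir = config$output_dir))
}

# nested-model x pollutant x window x form table, Rubin-pooled over the
# imputed datasets
.fit_battery <- function(wide_m, models, pollutants, windows) {
  rows <- list()
  z <- stats::qnorm(0.975)
  for (mdl in models) for (pol in pollutants) for (w in windows) {
    key <- paste0(pol, "_", w)
    iqr <- stats::IQR(wide_m[[1]][[key]])
    for (form in c("iqr", "quartile")) {
      fits <- lapply(wide_m, function(d)
        suppressWarnings(fit_cox(d, key, model = mdl, form = form,
                                 iqr = iqr)))
      e1 <- exposure_hr(fits[[1]])
      for (term in e1$term) {
        est <- vapply(fits, function(f) {
          e <- exposure_hr(f); e$estimate[e$term == term] }, numeric(1))
        ses <- vapply(fits, function(f) {
          e <- exposure_hr(f); e$se[e$term == term] }, numeric(1))
        pl <- pool_rubin(est, ses)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl, pollutant = pol, window = w, form = form,
          term = term, estimate = pl$estimate, se = pl$se,
          hr = exp(pl$estimate), lo = exp(pl$estimate - z * pl$se),
          hi = exp(pl$estimate + z * pl$se),
          n = fits[[1]]$n, nevent = fits[[1]]$nevent)
      }
    }
  }
  do.call(rbind, rows)
}

.config_digestible <- function(config) {
  cc <- config$cohort
  list(cohort = if (inherits(cc, "cohort_config"))
    lapply(unclass(cc), function(v)
      if (inherits(v, "Date")) format(v) else v)
    else cc[c("participants", "activity")],
    windows = config$windows, models = config$models,
    pollutants = config$pollutants,
    mixture_pollutants = config$mixture_pollutants,
    sensitivity = config$sensitivity, subgroups = config$subgroups,
    if_home = config$ift$if_home,
    if_transit = as.vector(config$ift$if_transit),
    m_imputations = config$m_imputations, seed = config$seed)
}
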