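#' Assemble a run configuration
#'
#' Collects every tunable of the analysis with its default, so a run can
#' be reproduced from its manifest alone. Defaults follow the package's
#' standard analysis: chronological brackets 12,000-5,000 cal BP (4,000
#' for region labels matching `late_bracket_patterns`, for areas where
#' farming arrived late), laboratory errors capped at 150 14C yr, 100-yr
#' hull step, 200 14C-yr site-phase binning, 1000 simulations.
#'
#' @param dates path to the date-table CSV.
#' @param curve path to the calibration-curve file.
#' @param out output directory.
#' @param seed integer seed recorded and used for every stochastic stage.
#' @param brackets c(old, young) default chronological window (cal BP).
#' @param late_bracket_young young bracket for late-arrival regions.
#' @param late_bracket_patterns character vector of regular expressions;
#'   region labels matching any of them use `late_bracket_young`.
#' @param max_error laboratory-error cap (14C yr).
#' @param outliers optional path to a file of lab codes to drop (one per
#'   line), the result of expert auditing; never automated.
#' @param hull_step,hull_range hull-series settings.
#' @param growth_frac,pause_len,min_total_growth pulse-detection settings.
#' @param h site-phase binning width (14C yr).
#' @param n_sim Monte-Carlo ensemble size.
#' @param splits optional path to a GeoJSON of cultural split lines
#'   (features with properties `region` and optionally `labels`).
#' @param rescale rescaling mode for reported SPDs.
#' @param taphonomy apply taphonomic correction to reported growth rates.
#' @param edge_margin years next to the brackets excluded from
#'   growth-rate fits (calibration edge effects).
#' @return list of class `run_config` with all defaults materialised.
#' @export
run_config <- function(dates = NULL, curve = NULL, out = ".", seed = 1L,
                       brackets = c(12000, 5000),
                       late_bracket_young = 4000,
                       late_bracket_patterns = character(0),
                       max_error = 150, outliers = NULL,
                       hull_step = 100, hull_range = c(12000, 4000),
                       growth_frac = 0.05, pause_len = 2L,
                       min_total_growth = 0.15, h = 200, n_sim = 1000L,
                       splits = NULL, rescale = "per-bin",
                       taphonomy = TRUE, edge_margin = 300) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a radiocarbon date table
#'
#' Reads the standard CSV schema (`lab_code`, `cra`, `sigma_lab`, `site`,
#' `lon`, `lat`, `period`, `culture`), renames `sigma_lab` to the internal
#' `error`, validates coordinates and applies the dataset-level filters:
#' rows with laboratory errors above `max_error` are dropped, as are lab
#' codes listed in the optional `outliers` file; the numbers excluded are
#' reported via `message()` and attached as attribute `filter_counts`.
#'
#' @param path CSV file.
#' @param max_error laboratory-error cap (14C yr, default 150).
#' @param outliers optional path to a newline-separated lab-code list.
#' @return data.frame of retained dates.
#' @export
read_dates <- function(path, max_error = 150, outliers = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_code", "cra", "sigma_lab", "site", "lon", "lat", "period")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("date table misses required columns: ", paste(miss, collapse = ", "))
  names(d)[names(d) == "sigma_lab"] <- "error"
  if (!"culture" %in% names(d)) d$culture <- NA_character_
  bad_coord <- is.na(d$lon) | is.na(d$lat) | abs(d$lat) > 90 | abs(d$lon) > 180
  bad_err <- is.na(d$error) | d$error <= 0
  n_over <- sum(d$error > max_error, na.rm = TRUE)
  keep <- !bad_coord & !bad_err & d$error <= max_error
  n_outlier <- 0L
  if (!is.null(outliers)) {
    drop_codes <- readLines(outliers, warn = FALSE)
    drop_codes <- trimws(drop_codes[nzchar(trimws(drop_codes))])
    n_outlier <- sum(keep & d$lab_code %in% drop_codes)
    keep <- keep & !d$lab_code %in% drop_codes
  }
  message(sprintf(
    "read %d dates: dropped %d with error > %d, %d invalid, %d outliers; %d retained",
    nrow(d), n_over, max_error, sum(bad_coord | bad_err), n_outlier,
    sum(keep)))
  out <- d[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(total = nrow(d), over_error = n_over,
                                  invalid = sum(bad_coord | bad_err),
                                  outliers = n_outlier,
                                  retained = sum(keep))
  out
}

write_manifest <- function(cfg, dir, stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     package_version = as.character(
                       utils::packageVersion("neofront"))),
                unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Calibrate a date table and store modes
#'
#' Pipeline stage: reads the dates and curve named in the config,
#' calibrates every date, appends the `mode_age` column and writes
#' `modes.csv` plus a reproducibility manifest to the output directory.
#' Rows whose CRA falls outside the curve span are logged and skipped.
#'
#' @param cfg a [run_config()] with `dates` and `curve` set.
#' @return the annotated date table, invisibly.
#' @export
run_calibrate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  d <- read_dates(cfg$dates, max_error = cfg$max_error,
                  outliers = cfg$outliers)
  if (!nrow(d)) stop("no dates retained after filtering")
  curve <- read_cal_curve(cfg$curve)
  d$mode_age <- .cal_modes_c(d$cra, d$error, curve$mu, curve$sigma,
                             as.numeric(curve$grid))
  n_bad <- sum(is.na(d$mode_age))
  if (n_bad)
    message(n_bad, " dates outside the curve span were skipped")
  d <- d[!is.na(d$mode_age), , drop = FALSE]
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  out <- d
  names(out)[names(out) == "error"] <- "sigma_lab"
  utils::write.csv(out, file.path(cfg$out, "modes.csv"), row.names = FALSE)
  write_manifest(cfg, cfg$out, "calibrate",
                 list(n_calibrated = nrow(d), n_skipped = n_bad))
  invisible(d)
}

#' Track the front and derive the region partition
#'
#' Pipeline stage: hull series over the configured range, pulse
#' detection, regionalisation and optional cultural splits. Writes
#' `hull_areas.csv` (the hull-area time series), `pulses.csv` and
#' `regions.geojson` to the output directory.
#'
#' @param cfg a [run_config()].
#' @param dates calibrated date table (from [run_calibrate()]); read from
#'   `<out>/modes.csv` when omitted.
#' @return list with `series`, `pulses`, `partition`, invisibly.
#' @export
run_front <- function(cfg, dates = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dates)) {
    dates <- utils::read.csv(file.path(cfg$out, "modes.csv"),
                             stringsAsFactors = FALSE)
    names(dates)[names(dates) == "sigma_lab"] <- "error"
  }
  if (sum(dates$period == "Neolithic") < 3L)
    stop("need at least 3 Neolithic dates for front tracking")
  hs <- hull_series(dates, step = cfg$hull_step, range = cfg$hull_range)
  pulses <- detect_pulses(hs, growth_frac = cfg$growth_frac,
                          pause_len = cfg$pause_len,
                          min_total_growth = cfg$min_total_growth)
  if (!nrow(pulses)) stop("no dispersal pulses detected")
  part <- region_polygons(hs, pulses)
  if (!is.null(cfg$splits)) {
    splits <- read_splits_geojson(cfg$splits)
    part <- apply_splits(part, splits)
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(tau = hs$tau, area_km2 = hs$area, n = hs$n),
                   file.path(cfg$out, "hull_areas.csv"), row.names = FALSE)
  utils::write.csv(pulses, file.path(cfg$out, "pulses.csv"),
                   row.names = FALSE)
  write_partition_geojson(part, file.path(cfg$out, "regions.geojson"))
  write_manifest(cfg, cfg$out, "front",
                 list(n_pulses = nrow(pulses),
                      n_regions = length(part$regions)))
  invisible(list(series = hs, pulses = pulses, partition = part))
}

# Split lines from a GeoJSON FeatureCollection of LineStrings with a
# `region` property (and optional `labels`).
read_splits_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) as.numeric(unlist(p))))
    list(region = f$properties$region, line = coords,
         labels = if (!is.null(f$properties$labels))
           as.character(unlist(f$properties$labels)) else NULL)
  })
}

#' Run the per-region Monte-Carlo SPD tests
#'
#' Pipeline stage: assigns dates to regions, then for each region runs
#' the MCSPD test (Mesolithic-only null, observed bin count, seeded
#' ensemble) and fits exponential growth rates with and without
#' taphonomic correction. Regions with an insufficient Mesolithic record
#' are skipped with an explicit log line. Per region, writes
#' `<label>.csv`/`<label>.json` result files plus `summary.csv`.
#'
#' @param cfg a [run_config()].
#' @param dates calibrated date table; read from `<out>/modes.csv` when
#'   omitted.
#' @param partition a `region_partition`; read from
#'   `<out>/regions.geojson` when omitted.
#' @return summary data.frame, invisibly.
#' @export
run_test <- function(cfg, dates = NULL, partition = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dates)) {
    dates <- utils::read.csv(file.path(cfg$out, "modes.csv"),
                             stringsAsFactors = FALSE)
    names(dates)[names(dates) == "sigma_lab"] <- "error"
  }
  if (is.null(partition))
    partition <- read_partition_geojson(file.path(cfg$out,
                                                  "regions.geojson"))
  curve <- read_cal_curve(cfg$curve)
  dates$region <- assign_regions(dates, partition)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in partition$regions) {
    dr <- dates[dates$region == r$label, , drop = FALSE]
    young <- if (length(cfg$late_bracket_patterns) &&
                 any(vapply(cfg$late_bracket_patterns,
                            function(p) grepl(p, r$label), TRUE)))
      cfg$late_bracket_young else cfg$brackets[2L]
    window <- c(cfg$brackets[1L], young)
    neolith <- if (r$pulse > 0L) r$start else NULL
    res <- tryCatch(
      mcspd_test(dr, curve, window = window, neolithization = neolith,
                 h = cfg$h, n_sim = cfg$n_sim,
                 seed = cfg$seed + r$pulse),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("region ", r$label, " skipped: ", conditionMessage(res))
      next
    }
    fit_win <- c(window[1L] - cfg$edge_margin, young + cfg$edge_margin)
    binned <- bin_dates(dr, h = cfg$h)
    s <- compute_spd(binned, curve, window = window, keep_bins = TRUE)
    gf <- tryCatch(fit_exponential(s, window = fit_win,
                                   seed = cfg$seed + r$pulse),
                   error = function(e) NULL)
    gf_tc <- if (cfg$taphonomy)
      tryCatch(fit_exponential(correct_taphonomy(s), window = fit_win,
                               n_boot = 0),
               error = function(e) NULL) else NULL
    write_mcspd_result(res, file.path(cfg$out, r$label))
    rows[[length(rows) + 1L]] <- data.frame(
      region = r$label, pulse = r$pulse, n_bins = res$n_bins,
      global_p = res$p,
      rate_pct = if (is.null(gf)) NA_real_ else gf$rate_pct,
      rate_se_pct = if (is.null(gf)) NA_real_ else gf$se_pct,
      rate_pct_taph = if (is.null(gf_tc)) NA_real_ else gf_tc$rate_pct,
      neolithization = res$neolithization)
  }
  if (!length(rows)) stop("no region could be tested")
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(cfg$out, "summary.csv"),
                   row.names = FALSE)
  write_manifest(cfg, cfg$out, "test",
                 list(n_regions_tested = nrow(summary)))
  invisible(summary)
}

#' Generate a synthetic dataset as a pipeline stage
#'
#' Writes a generated world (dates CSV, toy curve, ground truth) to the
#' configured output directory together with a manifest.
#'
#' @param cfg a [run_config()]; `cfg$seed` seeds the world.
#' @param ... passed to [world_config()].
#' @return the `synthetic_world`, invisibly.
#' @export
run_simulate <- function(cfg, ...) {
  stopifnot(inherits(cfg, "run_config"))
  world <- generate_world(world_config(seed = cfg$seed, ...))
  write_world(world, cfg$out)
  write_manifest(cfg, cfg$out, "simulate",
                 list(n_dates = nrow(world$dates)))
  invisible(world)
}
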