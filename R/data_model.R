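#' Construct a stem-radius series
#'
#' A radius series holds micrometre displacements of the stem surface relative
#' to the sensor installation point, on a nominal 10-min (or hourly) grid, in
#' local standard time without DST shifts. Because the zero-growth rule is
#' translation-invariant, only displacements (not absolute radii) are stored;
#' values may be negative.
#'
#' @param series_id Character scalar identifying the dendrometer series.
#' @param timestamp POSIXct vector, strictly increasing.
#' @param value_um Numeric radius displacement in micrometres.
#' @param flag Per-point quality flag, one of `"ok"`, `"outlier"`,
#'   `"shift_corrected"`, `"gap_filled"`.
#' @param tree_id Optional tree identifier (defaults to `series_id`).
#' @return A data frame of class `radius_series` with columns `series_id`,
#'   `timestamp`, `value_um`, `flag`.
#' @export
radius_series <- function(series_id, timestamp, value_um,
                          flag = rep("ok", length(timestamp)),
                          tree_id = series_id) {
  if (length(series_id) != 1L) stop_dd("radius_series: series_id must be scalar")
  if (length(timestamp) != length(value_um) || length(flag) != length(value_um))
    stop_dd("radius_series: timestamp, value_um, flag must have equal length")
  if (length(timestamp) > 0 && any(diff(as.numeric(timestamp)) <= 0))
    stop_dd("radius_series '%s': timestamps must be strictly increasing", series_id)
  bad <- setdiff(unique(flag), c("ok", "outlier", "shift_corrected", "gap_filled"))
  if (length(bad) > 0)
    stop_dd("radius_series '%s': unknown quality flag(s): %s", series_id,
            paste(bad, collapse = ", "))
  out <- data.frame(series_id = series_id,
                    timestamp = timestamp,
                    value_um = as.numeric(value_um),
                    flag = as.character(flag),
                    stringsAsFactors = FALSE)
  attr(out, "tree_id") <- tree_id
  class(out) <- c("radius_series", "data.frame")
  out
}

#' Construct an environmental series
#'
#' Hourly air temperature, relative humidity, vapour pressure deficit and soil
#' water potential for one site. VPD is recomputed from temperature and
#' humidity (Magnus form, see [compute_vpd()]) when not supplied. Small
#' positive SWP readings (sensor noise) are clamped to 0 with a warning;
#' values below -1e5 kPa are rejected as non-physical.
#'
#' @param site_id Character scalar.
#' @param timestamp POSIXct vector (hourly instants), strictly increasing.
#' @param temp_c Air temperature, degrees Celsius.
#' @param relh_pct Relative humidity, percent, in \[0, 100\].
#' @param vpd_kpa Vapour pressure deficit, kPa (optional; computed if `NULL`).
#' @param swp_kpa Soil water potential, kPa, non-positive (optional).
#' @param net_radiation Net radiation, W m^-2 (optional).
#' @param clamp_swp Clamp small positive SWP to 0 instead of erroring.
#' @return A data frame of class `env_series`.
#' @export
env_series <- function(site_id, timestamp, temp_c, relh_pct,
                       vpd_kpa = NULL, swp_kpa = NULL, net_radiation = NULL,
                       clamp_swp = TRUE) {
  if (length(site_id) != 1L) stop_dd("env_series: site_id must be scalar")
  n <- length(timestamp)
  if (length(temp_c) != n || length(relh_pct) != n)
    stop_dd("env_series '%s': column lengths differ", site_id)
  if (n > 0 && any(diff(as.numeric(timestamp)) <= 0))
    stop_dd("env_series '%s': timestamps must be strictly increasing", site_id)
  if (any(relh_pct < 0 | relh_pct > 100, na.rm = TRUE))
    stop_dd("env_series '%s': relh_pct outside [0, 100]", site_id)
  if (is.null(vpd_kpa)) vpd_kpa <- compute_vpd(temp_c, relh_pct)
  if (any(vpd_kpa < 0, na.rm = TRUE))
    stop_dd("env_series '%s': vpd_kpa must be >= 0", site_id)
  if (!is.null(swp_kpa)) {
    if (any(swp_kpa < -1e5, na.rm = TRUE))
      stop_dd("env_series '%s': swp_kpa below -1e5 kPa is non-physical", site_id)
    pos <- !is.na(swp_kpa) & swp_kpa > 0
    if (any(pos)) {
      if (!clamp_swp)
        stop_dd("env_series '%s': positive swp_kpa", site_id)
      warn_dd("env_series '%s': %d positive SWP reading(s) clamped to 0",
              site_id, sum(pos))
      swp_kpa[pos] <- 0
    }
  } else {
    swp_kpa <- rep(NA_real_, n)
  }
  out <- data.frame(site_id = site_id, timestamp = timestamp,
                    temp_c = as.numeric(temp_c),
                    relh_pct = as.numeric(relh_pct),
                    vpd_kpa = as.numeric(vpd_kpa),
                    swp_kpa = as.numeric(swp_kpa),
                    net_radiation = if (is.null(net_radiation)) NA_real_
                                    else as.numeric(net_radiation),
                    stringsAsFactors = FALSE)
  class(out) <- c("env_series", "data.frame")
  out
}

#' Construct tree metadata
#'
#' One row per dendrometer series, resolving each `series_id` to a tree,
#' species and site (the nested design: trees and species within sites).
#'
#' @param series_id,tree_id,species,site_id Character vectors of equal length.
#' @param installation_date Optional POSIXct/Date vector.
#' @return A data frame of class `tree_meta`.
#' @export
tree_meta <- function(series_id, tree_id, species, site_id,
                      installation_date = NULL) {
  n <- length(series_id)
  if (anyDuplicated(series_id))
    stop_dd("tree_meta: duplicate series_id (each series must resolve to exactly one tree)")
  out <- data.frame(series_id = as.character(series_id),
                    tree_id = as.character(tree_id),
                    species = as.character(species),
                    site_id = as.character(site_id),
                    stringsAsFactors = FALSE)
  out$installation_date <- if (is.null(installation_date)) as.POSIXct(rep(NA, n)) else installation_date
  class(out) <- c("tree_meta", "data.frame")
  out
}

#' Create an empty run report
#'
#' A run report accumulates the configuration snapshot, seed, per-stage record
#' counts, filter tallies and warnings of a pipeline run; runs with identical
#' config and seed produce identical reports.
#'
#' @param config List; configuration snapshot.
#' @param seed Integer seed of the run.
#' @return A list of class `run_report`.
#' @export
run_report <- function(config = list(), seed = NA_integer_) {
  structure(list(config = config, seed = seed,
                 stages = list(), tallies = list(), warnings = character(0)),
            class = "run_report")
}

#' @rdname run_report
#' @param report A `run_report`.
#' @param stage Stage name.
#' @param counts Named list/vector of record counts for the stage.
#' @export
report_stage <- function(report, stage, counts) {
  report$stages[[stage]] <- as.list(counts)
  report
}

#' Serialize / deserialize a run report as JSON
#' @param report A `run_report`.
#' @param path File path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}
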