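# CSV readers and writers for the pipeline's external interfaces.
# All files are UTF-8, comma-separated, '.' decimal, ISO-8601 timestamps.
# Numeric round-trips are exact to 6 significant digits (write precision is
# 15 significant digits, so in practice reads reproduce writes bit-for-bit
# for values of typical magnitude).

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_dd("%s: file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_cols(df, required, what)
  df
}

parse_timestamp_col <- function(x, path, what) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2})?)?$", x)
  if (any(!ok))
    stop_dd("%s: unparseable timestamp '%s' at data row %d of %s",
            what, x[which(!ok)[1]], which(!ok)[1], path)
  parse_timestamp(x)
}

#' Read dendrometer radius series from CSV
#'
#' Expects header columns `series_id,timestamp,value_um` (ISO-8601
#' timestamps). Rows are sorted per series; duplicated
#' (series_id, timestamp) pairs are rejected.
#'
#' @param path CSV file path.
#' @return Named list of [radius_series()] objects, one per `series_id`.
#' @export
read_radius_csv <- function(path) {
  df <- read_csv_checked(path, c("series_id", "timestamp", "value_um"),
                         "read_radius_csv")
  df$timestamp <- parse_timestamp_col(df$timestamp, path, "read_radius_csv")
  dup <- duplicated(df[c("series_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_dd("read_radius_csv: duplicated (series_id, timestamp) = ('%s', %s)",
            df$series_id[i], format_timestamp(df$timestamp[i]))
  }
  has_flag <- "quality_flag" %in% names(df)
  out <- lapply(split(df, df$series_id), function(d) {
    d <- d[order(d$timestamp), ]
    radius_series(d$series_id[1], d$timestamp, d$value_um,
                  flag = if (has_flag) d$quality_flag else rep("ok", nrow(d)))
  })
  out[order(names(out))]
}

#' Read environmental series from CSV
#'
#' Expects columns `site_id,timestamp,temp_c,relh_pct` with optional
#' `vpd_kpa`, `swp_kpa`, `net_radiation`. VPD is computed from temperature
#' and humidity when absent. Validation and SWP clamping as in
#' [env_series()].
#'
#' @param path CSV file path.
#' @param clamp_swp Clamp small positive SWP readings to 0 (warning) instead
#'   of erroring.
#' @return Named list of [env_series()] objects, one per `site_id`.
#' @export
read_env_csv <- function(path, clamp_swp = TRUE) {
  df <- read_csv_checked(path, c("site_id", "timestamp", "temp_c", "relh_pct"),
                         "read_env_csv")
  df$timestamp <- parse_timestamp_col(df$timestamp, path, "read_env_csv")
  lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$timestamp), ]
    env_series(d$site_id[1], d$timestamp, d$temp_c, d$relh_pct,
               vpd_kpa = d[["vpd_kpa"]], swp_kpa = d[["swp_kpa"]],
               net_radiation = d[["net_radiation"]], clamp_swp = clamp_swp)
  })
}

#' Read tree/site metadata from CSV
#'
#' Expects columns `series_id,tree_id,species,site_id` with optional
#' `installation_date`.
#'
#' @param path CSV file path.
#' @return A [tree_meta()] data frame.
#' @export
read_meta_csv <- function(path) {
  df <- read_csv_checked(path, c("series_id", "tree_id", "species", "site_id"),
                         "read_meta_csv")
  inst <- if ("installation_date" %in% names(df))
    parse_timestamp_col(df$installation_date, path, "read_meta_csv") else NULL
  tree_meta(df$series_id, df$tree_id, df$species, df$site_id, inst)
}

write_table_csv <- function(df, path) {
  ts_cols <- vapply(df, inherits, logical(1), what = "POSIXct")
  for (cl in names(df)[ts_cols]) df[[cl]] <- format_timestamp(df[[cl]])
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline objects to CSV
#'
#' Writers for the standard long-format interchange files: radius series
#' (`series_id,timestamp,value_um,quality_flag`), environmental series,
#' growth partitions
#' (`series_id,timestamp,radius_um,run_max_um,gro_inc_um,gro_cum_um,twd_um,is_growth_hour,ambiguous_flag`),
#' diel profiles and response grids. `read_*` of a written file reproduces
#' the object up to float formatting.
#'
#' @param x Object or list of objects of the matching class.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_radius_csv <- function(x, path) {
  if (inherits(x, "radius_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(series_id = s$series_id, timestamp = s$timestamp,
               value_um = s$value_um, quality_flag = s$flag)))
  write_table_csv(df, path)
}

#' @rdname write_radius_csv
#' @export
write_env_csv <- function(x, path) {
  if (inherits(x, "env_series")) x <- list(x)
  write_table_csv(do.call(rbind, lapply(x, as.data.frame)), path)
}

#' @rdname write_radius_csv
#' @export
write_partition_csv <- function(x, path) {
  if (inherits(x, "growth_partition")) x <- list(x)
  write_table_csv(do.call(rbind, lapply(x, as.data.frame)), path)
}

#' @rdname write_radius_csv
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "diel_profile")) x <- list(x)
  parts <- lapply(x, function(p) {
    d <- as.data.frame(p)
    cbind(data.frame(level = attr(p, "level"), id = attr(p, "id")), d,
          data.frame(n_units = attr(p, "n_units")))
  })
  cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(d) {
    d[setdiff(cols, names(d))] <- NA_real_
    d[cols]
  })
  write_table_csv(do.call(rbind, parts), path)
}

#' @rdname write_radius_csv
#' @export
write_grid_csv <- function(x, path) {
  write_table_csv(as.data.frame(x), path)
}

#' @rdname write_radius_csv
#' @export
write_meta_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (all(is.na(df$installation_date))) df$installation_date <- NULL
  write_table_csv(df, path)
}
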