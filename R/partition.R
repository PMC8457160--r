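#' Zero-growth partitioning of a stem-radius series
#'
#' Separates a dendrometer radius series into irreversible growth (GRO) and
#' tree water deficit (TWD) under the zero-growth rule: no growth occurs while
#' the stem is below its previous maximum radius. With the running maximum
#' M(t) = max(r(u), u <= t) initialized at the first observation,
#' \deqn{GRO_{inc}(t) = M(t) - M(t-1) \ge 0, \quad TWD(t) = M(t) - r(t) \ge 0,}
#' so that r(t) - r(t0) = GRO_cum(t) - TWD(t) exactly (TWD(t0) = 0). When the
#' radius exactly meets its previous maximum, TWD = 0 and GRO increment 0 (not
#' a growth hour). The running maximum persists across data gaps; growth
#' detected immediately after a gap longer than `ambiguous_gap` is real but of
#' uncertain timing and is flagged ambiguous.
#'
#' The partition is translation-invariant: `zg_partition(r + c)` equals
#' `zg_partition(r)` for any constant baseline shift.
#'
#' @param series A [radius_series()] at any resolution; increments can later
#'   be aggregated per hour with [partition_to_hourly()].
#' @param ambiguous_gap Gap duration (seconds) beyond which post-gap growth is
#'   flagged ambiguous. Default 6 hours.
#' @return A data frame of class `growth_partition` with columns `series_id`,
#'   `timestamp`, `radius_um`, `run_max_um`, `gro_inc_um`, `gro_cum_um`,
#'   `twd_um`, `is_growth_hour`, `ambiguous_flag`.
#' @export
zg_partition <- function(series, ambiguous_gap = 6 * 3600) {
  stopifnot(inherits(series, "radius_series"))
  n <- nrow(series)
  if (n == 0L) stop_dd("zg_partition: empty series")
  r <- series$value_um
  run_max <- cummax(r)
  gro_inc <- c(0, diff(run_max))
  gro_cum <- run_max - run_max[1]
  twd <- run_max - r
  gap_before <- c(0, diff(as.numeric(series$timestamp)))
  ambiguous <- gro_inc > 0 & gap_before > ambiguous_gap
  out <- data.frame(series_id = series$series_id,
                    timestamp = series$timestamp,
                    radius_um = r,
                    run_max_um = run_max,
                    gro_inc_um = gro_inc,
                    gro_cum_um = gro_cum,
                    twd_um = twd,
                    is_growth_hour = gro_inc > 0,
                    ambiguous_flag = ambiguous,
                    stringsAsFactors = FALSE)
  attr(out, "tree_id") <- attr(series, "tree_id")
  class(out) <- c("growth_partition", "data.frame")
  out
}

#' Aggregate a sub-hourly partition to hourly increments
#'
#' Sums growth increments of a native-resolution (e.g. 10-min) partition into
#' hours. Each increment measures growth over the span since the previous
#' observation, so it is attributed to the hour containing the span's
#' midpoint: for a regular 10-min grid, hour h collects the increments ending
#' at h:10 through (h+1):00, i.e. exactly the growth between h:00 and
#' (h+1):00. Radius, running maximum and TWD are taken at the last
#' observation of each bin, so the conservation identity
#' r(t) - r(t0) = GRO_cum - TWD is preserved exactly on the hourly grid.
#'
#' @param p A `growth_partition` at sub-hourly resolution.
#' @return An hourly `growth_partition`.
#' @export
partition_to_hourly <- function(p) {
  stopifnot(inherits(p, "growth_partition"))
  step <- stats::median(diff(as.numeric(p$timestamp)))
  key <- as.numeric(floor_hour(p$timestamp - step / 2))
  last <- !duplicated(key, fromLast = TRUE)
  inc <- tapply(p$gro_inc_um, key, sum)
  ambiguous <- tapply(p$ambiguous_flag, key, any)
  out <- data.frame(series_id = p$series_id[last],
                    timestamp = as.POSIXct(unique(key), origin = "1970-01-01",
                                           tz = "UTC"),
                    radius_um = p$radius_um[last],
                    run_max_um = p$run_max_um[last],
                    gro_inc_um = as.numeric(inc),
                    gro_cum_um = cumsum(as.numeric(inc)),
                    twd_um = p$twd_um[last],
                    is_growth_hour = as.numeric(inc) > 0,
                    ambiguous_flag = as.logical(ambiguous),
                    stringsAsFactors = FALSE)
  attr(out, "tree_id") <- attr(p, "tree_id")
  class(out) <- c("growth_partition", "data.frame")
  out
}

#' Count growth hours in a year
#'
#' Number of hours with a positive growth increment in the given calendar
#' year, optionally restricted to a detected growth period.
#'
#' @param p A `growth_partition` (hourly).
#' @param year Calendar year (integer).
#' @param period Optional one-row growth-period record (columns `start`,
#'   `end`) restricting the count.
#' @return Integer count of growth hours.
#' @export
growth_hours_per_year <- function(p, year, period = NULL) {
  stopifnot(inherits(p, "growth_partition"))
  sel <- year_of(p$timestamp) == year & p$is_growth_hour
  if (!is.null(period))
    sel <- sel & p$timestamp >= period$start & p$timestamp <= period$end
  sum(sel)
}
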