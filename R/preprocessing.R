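#' Cleaning configuration for raw dendrometer series
#'
#' Parameters of the simplified three-step cleaner ([clean_series()]):
#' spike (outlier) removal, sensor-shift correction, and short-gap filling.
#'
#' @param spike_window Odd number of points for the running median / MAD
#'   window. Default 7 (70 min at the native 10-min resolution).
#' @param spike_mad_factor A point is an outlier when its absolute deviation
#'   from the running median exceeds this multiple of the local MAD. Default 7.
#' @param shift_threshold_um Single-step jumps larger than this (in
#'   micrometres) that are not reversed within `spike_window` points are
#'   treated as sensor shifts. Default 50.
#' @param max_gap_fill Maximum gap duration (seconds, or a `difftime`) filled
#'   by linear interpolation. Default 3 hours.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(spike_window = 7L, spike_mad_factor = 7,
                            shift_threshold_um = 50, max_gap_fill = 3 * 3600) {
  spike_window <- as.integer(spike_window)
  if (spike_window < 3L || spike_window %% 2L == 0L)
    stop_dd("cleaning_config: spike_window must be odd and >= 3")
  if (spike_mad_factor <= 0 || shift_threshold_um <= 0)
    stop_dd("cleaning_config: factors and thresholds must be strictly positive")
  max_gap_fill <- as.numeric(max_gap_fill, units = "secs")
  if (max_gap_fill <= 0) stop_dd("cleaning_config: max_gap_fill must be positive")
  structure(list(spike_window = spike_window,
                 spike_mad_factor = spike_mad_factor,
                 shift_threshold_um = shift_threshold_um,
                 max_gap_fill = max_gap_fill),
            class = "cleaning_config")
}

#' Clean a raw dendrometer series
#'
#' Simplified quality processing of raw 10-min dendrometer data in three
#' passes: (1) points deviating from the running median over `spike_window`
#' points by more than `spike_mad_factor` times the local MAD are flagged
#' `outlier` and removed; (2) a single-step jump larger than
#' `shift_threshold_um` that is not reversed within `spike_window` points is
#' treated as a sensor shift and all subsequent values are offset back,
#' flagged `shift_corrected`; (3) gaps no longer than `max_gap_fill` are
#' linearly interpolated and flagged `gap_filled`, longer gaps remain gaps.
#'
#' @param raw A [radius_series()].
#' @param cfg A [cleaning_config()].
#' @return A cleaned [radius_series()].
#' @export
clean_series <- function(raw, cfg = cleaning_config()) {
  stopifnot(inherits(raw, "radius_series"))
  n <- nrow(raw)
  if (n < cfg$spike_window)
    stop_dd("clean_series '%s': series shorter than spike_window (%d < %d)",
            raw$series_id[1], n, cfg$spike_window)

  ts <- raw$timestamp
  v <- raw$value_um

  # 1. spike removal ---------------------------------------------------------
  med <- stats::runmed(v, cfg$spike_window, endrule = "median")
  dev <- abs(v - med)
  # local MAD floored by the series-wide MAD: the nested running median
  # degenerates to zero wherever the window median coincides with a data
  # value, so the global scale guards against spurious flags in quiet spans
  local_mad <- 1.4826 * stats::runmed(dev, cfg$spike_window, endrule = "median")
  global_mad <- 1.4826 * stats::median(dev)
  spike <- dev > cfg$spike_mad_factor * pmax(local_mad, global_mad, 1e-9) &
           dev > 1e-9  # a flat series is never all-outlier
  if (all(spike))
    stop_dd("clean_series '%s': all points flagged as outliers", raw$series_id[1])
  ts <- ts[!spike]; v <- v[!spike]

  # 2. shift correction ------------------------------------------------------
  flag <- rep("ok", length(v))
  i <- 1L
  while (i < length(v)) {
    d <- v[i + 1L] - v[i]
    if (abs(d) > cfg$shift_threshold_um) {
      horizon <- seq(i + 1L, min(length(v), i + cfg$spike_window))
      reversed <- any(abs(v[horizon] - v[i]) < cfg$shift_threshold_um / 2)
      if (!reversed) {
        v[(i + 1L):length(v)] <- v[(i + 1L):length(v)] - d
        flag[(i + 1L):length(v)] <- "shift_corrected"
      }
    }
    i <- i + 1L
  }

  # 3. gap filling on the nominal grid --------------------------------------
  step <- stats::median(diff(as.numeric(ts)))
  grid <- seq(ts[1], ts[length(ts)], by = step)
  idx <- match(as.numeric(grid), as.numeric(ts))
  gv <- v[idx]; gf <- flag[idx]
  missing <- is.na(idx)
  if (any(missing)) {
    runs <- rle(missing)
    fillable <- rep(runs$values & runs$lengths * step <= cfg$max_gap_fill,
                    runs$lengths)
    if (any(fillable)) {
      interp <- stats::approx(as.numeric(grid[!missing]), gv[!missing],
                              xout = as.numeric(grid[fillable]))$y
      gv[fillable] <- interp
      gf[fillable] <- "gap_filled"
    }
    keep <- !missing | fillable
    grid <- grid[keep]; gv <- gv[keep]; gf <- gf[keep]
  }

  radius_series(raw$series_id[1], grid, gv, flag = gf,
                tree_id = attr(raw, "tree_id"))
}

#' Aggregate a radius series to hourly means
#'
#' One value per hour-of-day interval \[h:00, h+1:00) equal to the arithmetic
#' mean of the available native-resolution values in that hour; hours with no
#' data are absent (never interpolated). The returned series carries an
#' `n_points` column with the count of contributing points per hour.
#'
#' @param series A (cleaned) [radius_series()].
#' @return An hourly [radius_series()] with an extra `n_points` column.
#' @export
to_hourly <- function(series) {
  stopifnot(inherits(series, "radius_series"))
  h <- floor_hour(series$timestamp)
  key <- as.numeric(h)
  means <- tapply(series$value_um, key, mean)
  counts <- tapply(series$value_um, key, length)
  ts <- as.POSIXct(as.numeric(names(means)), origin = "1970-01-01", tz = "UTC")
  out <- radius_series(series$series_id[1], ts, as.numeric(means),
                       tree_id = attr(series, "tree_id"))
  out$n_points <- as.integer(counts)
  out
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD = es(T) (1 - RH/100) with the Magnus (Tetens) saturation vapour
#' pressure over water, es(T) = 0.6108 exp(17.27 T / (T + 237.3)) kPa - the
#' standard ecophysiological form. Constants are exposed for substitution.
#'
#' @param temp_c Air temperature, degrees Celsius.
#' @param relh_pct Relative humidity, percent, in \[0, 100\].
#' @param a,b,c Magnus constants (kPa, -, degrees C).
#' @return VPD in kPa (>= 0), vectorized.
#' @export
#' @examples
#' compute_vpd(20, 100)  # saturated air: 0
#' compute_vpd(20, 50)   # ~1.169 kPa
compute_vpd <- function(temp_c, relh_pct, a = 0.6108, b = 17.27, c = 237.3) {
  if (any(relh_pct < 0 | relh_pct > 100, na.rm = TRUE))
    stop_dd("compute_vpd: relh_pct outside [0, 100]")
  es <- a * exp(b * temp_c / (temp_c + c))
  pmax(es * (1 - relh_pct / 100), 0)
}
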