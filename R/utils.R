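# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All timestamps in the package are local standard time without DST,
# represented as POSIXct in the fixed "UTC" zone. Hour-of-day h labels the
# interval [h:00, h+1:00).
parse_timestamp <- function(x) {
  as.POSIXct(sub("T", " ", x), tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

hour_of <- function(ts) as.POSIXlt(ts, tz = "UTC")$hour

year_of <- function(ts) as.POSIXlt(ts, tz = "UTC")$year + 1900L

doy_of <- function(ts) as.POSIXlt(ts, tz = "UTC")$yday + 1L

floor_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# type-7 (linear interpolation) quantiles, the package-wide convention
q25 <- function(x) unname(stats::quantile(x, 0.25, type = 7, names = FALSE, na.rm = TRUE))
q75 <- function(x) unname(stats::quantile(x, 0.75, type = 7, names = FALSE, na.rm = TRUE))

stop_dd <- function(...) stop(sprintf(...), call. = FALSE)

warn_dd <- function(...) warning(sprintf(...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_dd("%s: missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  invisible(df)
}
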