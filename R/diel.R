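#' Diel growth profile of a single tree
#'
#' Step 1 of the nested aggregation. For each year within the detected growth
#' period, the relative contribution of hour-of-day h to annual growth is
#' \deqn{contribution\_pct[h] = 100 \frac{\sum_{t \in h} GRO_{inc}(t)}
#'       {\sum_t GRO_{inc}(t)},}
#' so the 24 bins of one tree-year sum to 100. Growth probability at h is the
#' percentage of period hours at that hour-of-day that are growth hours, and
#' the hourly growth rate is the median increment over growth hours at h (in
#' um/h, not normalized). Multi-year trees average the yearly contribution and
#' probability vectors arithmetically and pool growth-hour increments across
#' years for the rate medians.
#'
#' With `probability_denominator = "all_hours"` the probability uses the total
#' number of period hours divided by 24 as denominator instead of the per
#' hour-of-day count (the alternative reading of "relative to the total number
#' of hours in the stem growth phase").
#'
#' @param p Hourly `growth_partition` of one tree.
#' @param periods [detect_growth_periods()] rows applying to this tree's
#'   site x species (one row per year).
#' @param probability_denominator `"per_hour_of_day"` (default) or
#'   `"all_hours"`.
#' @return A data frame of class `diel_profile` (24 rows: `hour`,
#'   `contribution_pct`, `probability_pct`, `rate_um_h`) with attributes
#'   `level = "tree"`, `id`, `n_units`.
#' @export
tree_diel_profile <- function(p, periods,
                              probability_denominator = c("per_hour_of_day", "all_hours")) {
  probability_denominator <- match.arg(probability_denominator)
  stopifnot(inherits(p, "growth_partition"))
  contrib <- list(); prob <- list(); rate_pool <- vector("list", 24)
  for (i in seq_len(nrow(periods))) {
    per <- periods[i, ]
    sel <- p$timestamp >= per$start & p$timestamp <= per$end &
           year_of(p$timestamp) == per$year
    if (!any(sel)) next
    sub <- p[sel, ]
    total <- sum(sub$gro_inc_um)
    if (total <= 0)
      stop_dd("tree_diel_profile '%s': zero annual growth in %d (should have been filtered)",
              p$series_id[1], per$year)
    hod <- hour_of(sub$timestamp)
    csum <- vapply(0:23, function(h) sum(sub$gro_inc_um[hod == h]), 0)
    contrib[[length(contrib) + 1L]] <- 100 * csum / total
    n_at <- vapply(0:23, function(h) sum(hod == h), 0)
    g_at <- vapply(0:23, function(h) sum(sub$is_growth_hour[hod == h]), 0)
    denom <- if (probability_denominator == "per_hour_of_day") n_at
             else rep(nrow(sub) / 24, 24)
    prob[[length(prob) + 1L]] <- ifelse(denom > 0, 100 * g_at / denom, NA_real_)
    for (h in 0:23)
      rate_pool[[h + 1L]] <- c(rate_pool[[h + 1L]],
                               sub$gro_inc_um[hod == h & sub$is_growth_hour])
  }
  if (length(contrib) == 0L)
    stop_dd("tree_diel_profile '%s': no data inside any growth period", p$series_id[1])
  out <- data.frame(
    hour = 0:23,
    contribution_pct = rowMeans(do.call(cbind, contrib)),
    probability_pct = rowMeans(do.call(cbind, prob), na.rm = TRUE),
    rate_um_h = vapply(rate_pool, function(x)
      if (length(x)) stats::median(x) else NA_real_, 0))
  structure(out, level = "tree", id = p$series_id[1],
            n_units = length(contrib),
            class = c("diel_profile", "data.frame"))
}

new_agg_profile <- function(df, level, id, n_units) {
  structure(df, level = level, id = id, n_units = n_units,
            class = c("diel_profile", "data.frame"))
}

#' Aggregate tree profiles through the nested design
#'
#' Step 2 averages the per-bin values arithmetically across the trees of each
#' site x species unit; step 3 takes per-bin medians with 25% and 75%
#' quantiles (linear-interpolation convention) across site x species units,
#' both per species and pooled over all units. Tree-level contributions sum to
#' 100 exactly; aggregated medians need not and are not renormalized.
#'
#' @param tree_profiles Named list of tree-level [tree_diel_profile()] outputs
#'   (names = series_id).
#' @param meta A [tree_meta()] table.
#' @return A list with `site_species` (named list of mean profiles),
#'   `species` (named list of median profiles with `*_q25`/`*_q75` columns)
#'   and `pooled` (one median profile).
#' @export
aggregate_profiles <- function(tree_profiles, meta) {
  stopifnot(length(tree_profiles) > 0)
  ids <- names(tree_profiles)
  key <- meta[match(ids, meta$series_id), c("site_id", "species")]
  unit <- paste(key$site_id, key$species, sep = ":")

  metrics <- c("contribution_pct", "probability_pct", "rate_um_h")
  site_species <- lapply(split(seq_along(ids), unit), function(ix) {
    df <- data.frame(hour = 0:23)
    for (m in metrics)
      df[[m]] <- rowMeans(vapply(tree_profiles[ix], function(p) p[[m]],
                                 numeric(24)), na.rm = TRUE)
    new_agg_profile(df, "site_species", unit[ix[1]], length(ix))
  })

  median_across <- function(units, level, id) {
    df <- data.frame(hour = 0:23)
    for (m in metrics) {
      mat <- vapply(units, function(p) p[[m]], numeric(24))
      mat <- matrix(mat, nrow = 24)
      df[[m]] <- apply(mat, 1, stats::median, na.rm = TRUE)
      df[[paste0(m, "_q25")]] <- apply(mat, 1, q25)
      df[[paste0(m, "_q75")]] <- apply(mat, 1, q75)
    }
    new_agg_profile(df, level, id, length(units))
  }

  unit_species <- vapply(strsplit(names(site_species), ":"), `[`, "", 2)
  by_species <- split(site_species, unit_species)
  species <- Map(function(us, nm) median_across(us, "species", nm),
                 by_species, names(by_species))
  pooled <- median_across(site_species, "pooled", "all")
  list(site_species = site_species, species = species, pooled = pooled)
}

#' Time of day of maximum and minimum diel growth
#'
#' Argmax / argmin over the 24 contribution bins of an aggregated profile;
#' ties break toward the earliest hour. An all-equal profile returns hour 0
#' for both with a degeneracy warning.
#'
#' @param profile A `diel_profile` (typically species level).
#' @return A list with `time_gro_max` and `time_gro_min` (hours 0-23).
#' @export
peak_timing <- function(profile) {
  v <- profile$contribution_pct
  if (max(v) - min(v) < 1e-12) {
    warn_dd("peak_timing: degenerate all-equal profile; returning hour 0")
    return(list(time_gro_max = 0L, time_gro_min = 0L))
  }
  list(time_gro_max = profile$hour[which.max(v)],
       time_gro_min = profile$hour[which.min(v)])
}
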