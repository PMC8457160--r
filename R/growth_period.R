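#' Detect the annual stem growth period for one site x species x year
#'
#' The growth period is the within-year interval holding the central mass of
#' cumulative annual growth, determined from the average of all trees of a
#' species at a site: each tree's cumulative annual growth curve is
#' normalized to its annual total, the normalized curves are averaged on a
#' common hourly grid, and the period runs from the first hour where the
#' averaged curve reaches `trim` (default 5%) to the first hour where it
#' reaches `1 - trim` (95%). Trimming the first and last 5% avoids isolated
#' out-of-season micro-increments dominating the timing.
#'
#' `rule = "time"` provides the calendar alternative: the period is the span
#' from first to last detected growth hour with `trim` of its *duration*
#' removed at each end.
#'
#' @param partitions List of hourly `growth_partition` objects, one per tree
#'   of the same site x species.
#' @param site_id,species,year Identifiers of the group.
#' @param trim Fraction trimmed at each end (default 0.05).
#' @param rule `"growth"` (default; trim by cumulative-growth mass) or
#'   `"time"` (trim by calendar duration).
#' @return A one-row data frame of class `growth_period` with columns
#'   `site_id`, `species`, `year`, `start`, `end`, and a `coverage` attribute
#'   holding per-tree data-coverage fractions inside the period. Returns
#'   `NULL` when the group has zero total growth in the year (the tree-years
#'   are then excluded downstream).
#' @export
detect_growth_period <- function(partitions, site_id, species, year,
                                 trim = 0.05, rule = c("growth", "time")) {
  rule <- match.arg(rule)
  yearly <- lapply(partitions, function(p) {
    p[year_of(p$timestamp) == year, , drop = FALSE]
  })
  yearly <- Filter(function(p) nrow(p) > 0 && sum(p$gro_inc_um) > 0, yearly)
  if (length(yearly) == 0L) return(NULL)

  grid <- sort(unique(as.numeric(do.call(c, lapply(yearly, function(p) p$timestamp)))))
  curves <- vapply(yearly, function(p) {
    cum <- cumsum(p$gro_inc_um)
    cum <- cum / cum[length(cum)]
    # step interpolation: 0 before first observation, 1 after the last
    stats::approx(as.numeric(p$timestamp), cum, xout = grid,
                  method = "constant", yleft = 0, yright = 1, rule = 2)$y
  }, numeric(length(grid)))
  avg <- rowMeans(curves)

  if (rule == "growth") {
    start <- grid[which(avg >= trim)[1]]
    end <- grid[which(avg >= 1 - trim)[1]]
  } else {
    rising <- which(c(avg[1] > 0, diff(avg) > 0))
    first <- grid[rising[1]]
    last <- grid[rising[length(rising)]]
    start <- first + trim * (last - first)
    end <- last - trim * (last - first)
  }
  out <- data.frame(site_id = site_id, species = species, year = year,
                    start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
                    end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC"),
                    stringsAsFactors = FALSE)
  cov <- vapply(partitions, function(p) {
    sel <- p$timestamp >= out$start & p$timestamp <= out$end
    n_hours <- floor(as.numeric(out$end - out$start, units = "hours")) + 1
    min(1, sum(sel) / n_hours)
  }, numeric(1))
  attr(out, "coverage") <- data.frame(series_id = names(partitions) %||%
                                        vapply(partitions, function(p) p$series_id[1], ""),
                                      coverage_fraction = as.numeric(cov),
                                      stringsAsFactors = FALSE)
  class(out) <- c("growth_period", "data.frame")
  out
}

#' Detect growth periods for every site x species x year group
#'
#' @param partitions Named list of hourly `growth_partition` objects
#'   (names = series_id).
#' @param meta A [tree_meta()] table resolving series to site and species.
#' @inheritParams detect_growth_period
#' @return A `growth_period` data frame with one row per group with nonzero
#'   growth, and a `coverage` attribute with one row per tree-year.
#' @export
detect_growth_periods <- function(partitions, meta, trim = 0.05,
                                  rule = c("growth", "time")) {
  rule <- match.arg(rule)
  years <- sort(unique(unlist(lapply(partitions, function(p) year_of(p$timestamp)))))
  groups <- unique(meta[c("site_id", "species")])
  rows <- list(); covs <- list()
  for (i in seq_len(nrow(groups))) {
    ids <- meta$series_id[meta$site_id == groups$site_id[i] &
                          meta$species == groups$species[i]]
    sub <- partitions[intersect(names(partitions), ids)]
    if (length(sub) == 0L) next
    for (yr in years) {
      rec <- detect_growth_period(sub, groups$site_id[i], groups$species[i],
                                  yr, trim = trim, rule = rule)
      if (is.null(rec)) next
      cv <- attr(rec, "coverage")
      cv$year <- yr
      rows[[length(rows) + 1L]] <- rec
      covs[[length(covs) + 1L]] <- cv
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, lapply(rows, function(r) { attributes(r)$coverage <- NULL; as.data.frame(r) }))
  attr(out, "coverage") <- do.call(rbind, covs)
  class(out) <- c("growth_period", "data.frame")
  out
}

#' Apply the study's inclusion filters to tree-years
#'
#' Drops, with a tallied reason for every exclusion:
#' \itemize{
#'   \item `min_annual_growth`: tree-years with annual increment at or below
#'     `min_annual_growth_um` (default 100 um/yr);
#'   \item `coverage`: annual series covering at most `min_coverage` (default
#'     90%) of the site x species growth period;
#'   \item `species_sites` / `series_years`: species present at fewer than
#'     `min_sites` sites (default 4, i.e. more than 3) or series with fewer
#'     than `min_years` years of data (default 3, i.e. more than 2);
#'   \item `site_individuals`: site x species groups with fewer than
#'     `min_trees_per_site` individuals (default 2).
#' }
#' All criteria are evaluated simultaneously on the unfiltered table, so the
#' surviving set is independent of evaluation order; a tree-year may carry
#' several reasons.
#'
#' @param meta A [tree_meta()] table.
#' @param partitions Named list of hourly `growth_partition` objects.
#' @param periods Output of [detect_growth_periods()].
#' @param min_annual_growth_um,min_coverage,min_sites,min_years,min_trees_per_site
#'   Filter thresholds; defaults are the network study's criteria. Set
#'   `min_sites = 1, min_years = 1` for small simulated designs.
#' @return A list with `kept` (surviving tree-year table with per-year growth
#'   statistics), `dropped` (excluded tree-years with `reasons`), and `tally`
#'   (named exclusion counts by reason).
#' @export
apply_inclusion_filters <- function(meta, partitions, periods,
                                    min_annual_growth_um = 100,
                                    min_coverage = 0.9,
                                    min_sites = 4L, min_years = 3L,
                                    min_trees_per_site = 2L) {
  cov <- attr(periods, "coverage")
  rows <- list()
  for (sid in names(partitions)) {
    m <- meta[meta$series_id == sid, , drop = FALSE]
    if (nrow(m) == 0L)
      stop_dd("apply_inclusion_filters: series '%s' has no metadata", sid)
    p <- partitions[[sid]]
    for (yr in sort(unique(year_of(p$timestamp)))) {
      per <- periods[periods$site_id == m$site_id & periods$species == m$species &
                     periods$year == yr, , drop = FALSE]
      if (nrow(per) == 0L) next  # no-period group: excluded upstream
      sel <- year_of(p$timestamp) == yr &
             p$timestamp >= per$start & p$timestamp <= per$end
      cv <- cov$coverage_fraction[cov$series_id == sid & cov$year == yr]
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sid, tree_id = m$tree_id, species = m$species,
        site_id = m$site_id, year = yr,
        annual_growth_um = sum(p$gro_inc_um[year_of(p$timestamp) == yr]),
        period_growth_um = sum(p$gro_inc_um[sel]),
        growth_hours = sum(p$is_growth_hour[sel]),
        coverage_fraction = if (length(cv) == 1) cv else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ty <- do.call(rbind, rows)

  # group-level census on the unfiltered table
  sites_per_species <- tapply(ty$site_id, ty$species,
                              function(x) length(unique(x)))
  years_per_series <- tapply(ty$year, ty$series_id,
                             function(x) length(unique(x)))
  grp <- paste(ty$site_id, ty$species)
  trees_per_group <- tapply(ty$tree_id, grp, function(x) length(unique(x)))

  reasons <- lapply(seq_len(nrow(ty)), function(i) {
    r <- character(0)
    if (ty$annual_growth_um[i] <= min_annual_growth_um) r <- c(r, "min_annual_growth")
    if (!is.na(ty$coverage_fraction[i]) && ty$coverage_fraction[i] <= min_coverage)
      r <- c(r, "coverage")
    if (sites_per_species[[ty$species[i]]] < min_sites) r <- c(r, "species_sites")
    if (years_per_series[[ty$series_id[i]]] < min_years) r <- c(r, "series_years")
    if (trees_per_group[[grp[i]]] < min_trees_per_site) r <- c(r, "site_individuals")
    r
  })
  drop <- lengths(reasons) > 0
  tally <- table(unlist(reasons))
  dropped <- ty[drop, , drop = FALSE]
  dropped$reasons <- vapply(reasons[drop], paste, "", collapse = ";")
  list(kept = ty[!drop, , drop = FALSE],
       dropped = dropped,
       tally = as.list(tally))
}
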