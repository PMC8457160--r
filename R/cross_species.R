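#' Published reference summary of species diel-growth characteristics
#'
#' Ships the published cross-species summary table for the seven temperate
#' species of the Swiss dendrometer network (median hourly growth rate over
#' growth hours `gro_hr` in um/h, hour-of-day of maximum/minimum diel growth
#' contribution `time_gro_max`/`time_gro_min`, adjusted R^2 of diel growth vs
#' diel VPD `r2_vpd`, median growth hours per year `h_gro_yr`, median annual
#' radial increment `gro_yr` in um), so the cross-species peak-timing
#' regressions can be exercised without access to the network's raw data.
#'
#' @return A data frame of class `species_summary` with one row per species.
#' @export
reference_species_summary <- function() {
  path <- system.file("extdata", "species_diel_summary_reference.csv",
                      package = "dendrodiel", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Per-species summary of diel and annual growth
#'
#' Builds one summary row per species from the pipeline outputs: median
#' hourly growth rate over growth hours (`gro_hr`), diel peak/trough timing
#' from the species-level profile, adjusted R^2 of the species diel growth
#' contribution against the species diel VPD profile (`r2_vpd`), and medians
#' with quartiles across tree-years of annual growth hours (`h_gro_yr`) and
#' annual increment within the growth period (`gro_yr`). Species with no
#' surviving tree-years are omitted with a warning.
#'
#' @param agg Output of [aggregate_profiles()].
#' @param joined Output of [join_growth_env()].
#' @param tree_years Surviving tree-year table (`kept` element of
#'   [apply_inclusion_filters()]).
#' @return A data frame of class `species_summary`.
#' @export
summarize_species <- function(agg, joined, tree_years) {
  all_species <- sort(unique(tree_years$species))
  rows <- list()
  for (sp in all_species) {
    prof <- agg$species[[sp]]
    if (is.null(prof)) {
      warn_dd("summarize_species: species '%s' has no aggregated profile; omitted", sp)
      next
    }
    pk <- peak_timing(prof)
    j <- joined[joined$species == sp, ]
    ty <- tree_years[tree_years$species == sp, ]
    # diel VPD profile aggregated like growth: site-unit means, species median
    unit <- paste(j$site_id, j$species)
    vpd_units <- vapply(split(j, unit), function(u)
      vapply(0:23, function(h) mean(u$vpd_kpa[u$hour == h], na.rm = TRUE), 0),
      numeric(24))
    vpd24 <- apply(matrix(vpd_units, nrow = 24), 1, stats::median, na.rm = TRUE)
    r2_vpd <- tryCatch(
      regress_diel(prof$contribution_pct, list(vpd = vpd24))$adj_r2,
      error = function(e) NA_real_)
    ghr <- j$gro_inc_um[j$is_growth_hour]
    rows[[sp]] <- data.frame(
      species = sp,
      gro_hr = stats::median(ghr),
      time_gro_max = pk$time_gro_max, time_gro_min = pk$time_gro_min,
      r2_vpd = r2_vpd,
      h_gro_yr = stats::median(ty$growth_hours),
      h_gro_yr_q25 = q25(ty$growth_hours), h_gro_yr_q75 = q75(ty$growth_hours),
      gro_yr = stats::median(ty$period_growth_um),
      gro_yr_q25 = q25(ty$period_growth_um), gro_yr_q75 = q75(ty$period_growth_um),
      n_tree_years = nrow(ty), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Cross-species regression of annual growth on diel peak timing
#'
#' Ordinary least squares of a species-level response (`h_gro_yr`, annual
#' growth hours, or `gro_yr`, annual increment) on the hour-of-day of maximum
#' diel growth (`time_gro_max`) across species medians. On the published
#' seven-species reference table this relationship is strongly negative for
#' both responses.
#'
#' @param summary A `species_summary` data frame.
#' @param response `"h_gro_yr"` or `"gro_yr"` (or any numeric column).
#' @return A list of class `cross_species_fit`: `response`, `slope`,
#'   `intercept`, `r2`, `adj_r2` (= 1 - (1 - R^2)(n - 1)/(n - 2)),
#'   `p_value` (two-sided t-test on the slope), `n`.
#' @export
regress_peak_time <- function(summary, response = c("h_gro_yr", "gro_yr")) {
  response <- match.arg(response, choices = c(response, names(summary)))
  if (nrow(summary) < 3L)
    stop_dd("regress_peak_time: need >= 3 species rows, have %d", nrow(summary))
  x <- summary$time_gro_max
  if (length(unique(x)) == 1L)
    stop_dd("regress_peak_time: degenerate regressor (all time_gro_max equal)")
  y <- summary[[response]]
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(response = response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                 p_value = unname(s$coefficients[2, 4]),
                 n = nrow(summary), fit = fit),
            class = "cross_species_fit")
}

#' @export
print.cross_species_fit <- function(x, ...) {
  cat(sprintf("Cross-species fit: %s ~ time_gro_max (n = %d species)\n",
              x$response, x$n))
  cat(sprintf("  slope %.3f  intercept %.1f  R2 %.3f  adj R2 %.3f  p %.4g\n",
              x$slope, x$intercept, x$r2, x$adj_r2, x$p_value))
  invisible(x)
}
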