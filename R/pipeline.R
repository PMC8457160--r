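#' Read a growth-partition CSV back into partition objects
#'
#' @param path CSV written by [write_partition_csv()].
#' @return Named list of `growth_partition` objects.
#' @export
read_partition_csv <- function(path) {
  df <- read_csv_checked(path, c("series_id", "timestamp", "radius_um",
                                 "run_max_um", "gro_inc_um", "gro_cum_um",
                                 "twd_um", "is_growth_hour", "ambiguous_flag"),
                         "read_partition_csv")
  df$timestamp <- parse_timestamp_col(df$timestamp, path, "read_partition_csv")
  df$is_growth_hour <- as.logical(df$is_growth_hour)
  df$ambiguous_flag <- as.logical(df$ambiguous_flag)
  lapply(split(df, df$series_id), function(d) {
    d <- d[order(d$timestamp), ]
    rownames(d) <- NULL
    class(d) <- c("growth_partition", "data.frame")
    d
  })
}

#' Downstream analysis from hourly partitions
#'
#' Runs growth-period detection, inclusion filtering, diel statistics with
#' the nested aggregation, the growth/environment join and the species
#' summary, starting from already-computed hourly partitions.
#'
#' @param partitions Named list of hourly `growth_partition` objects.
#' @param env Named list of [env_series()] (names = site_id).
#' @param meta A [tree_meta()] table.
#' @param period_rule,period_trim Passed to [detect_growth_periods()].
#' @param probability_denominator Passed to [tree_diel_profile()].
#' @param filters Named list of threshold overrides for
#'   [apply_inclusion_filters()]. The default
#'   `list(min_sites = 1, min_years = 1)` suits small simulated designs; pass
#'   an empty list for the full network criteria.
#' @return A list with `periods`, `filters`, `profiles`, `agg`, `joined`,
#'   `summary`.
#' @export
analyze_partitions <- function(partitions, env, meta,
                               period_rule = c("growth", "time"),
                               period_trim = 0.05,
                               probability_denominator = c("per_hour_of_day", "all_hours"),
                               filters = list(min_sites = 1L, min_years = 1L)) {
  period_rule <- match.arg(period_rule)
  probability_denominator <- match.arg(probability_denominator)
  periods <- detect_growth_periods(partitions, meta,
                                   trim = period_trim, rule = period_rule)
  if (is.null(periods)) stop_dd("analyze_partitions: no growth detected anywhere")

  fargs <- c(list(meta = meta, partitions = partitions, periods = periods),
             filters)
  filt <- do.call(apply_inclusion_filters, fargs)
  if (nrow(filt$kept) == 0L)
    stop_dd("analyze_partitions: no tree-years survive the inclusion filters")

  kept_series <- unique(filt$kept$series_id)
  profiles <- lapply(stats::setNames(kept_series, kept_series), function(sid) {
    m <- meta[meta$series_id == sid, ]
    yrs <- filt$kept$year[filt$kept$series_id == sid]
    per <- periods[periods$site_id == m$site_id & periods$species == m$species &
                   periods$year %in% yrs, , drop = FALSE]
    tree_diel_profile(partitions[[sid]], per,
                      probability_denominator = probability_denominator)
  })
  agg <- aggregate_profiles(profiles, meta)

  kept_periods <- periods[paste(periods$site_id, periods$species, periods$year) %in%
                          paste(filt$kept$site_id, filt$kept$species, filt$kept$year), ,
                          drop = FALSE]
  joined <- join_growth_env(partitions[kept_series], env, meta, kept_periods)
  summary <- summarize_species(agg, joined, filt$kept)
  list(periods = periods, filters = filt, profiles = profiles, agg = agg,
       joined = joined, summary = summary)
}

#' Full in-memory analysis of a forest
#'
#' Convenience front-end chaining optional cleaning, hourly aggregation and
#' zero-growth partitioning into [analyze_partitions()].
#'
#' @param forest A `synthetic_forest` or a list with `dendro` (named list of
#'   [radius_series()]), `env` (named list of [env_series()]) and `meta`
#'   ([tree_meta()]).
#' @param clean Apply [clean_series()] to the raw series (default TRUE).
#' @param cleaning A [cleaning_config()].
#' @param partition_resolution `"hourly"` (default: partition the hourly-mean
#'   series, as the published analyses do) or `"native"` (partition at native
#'   resolution, then sum increments per hour -- sharper hour attribution).
#' @inheritParams analyze_partitions
#' @return As [analyze_partitions()], plus `cleaned`, `hourly`, `partitions`
#'   and `report`.
#' @export
analyze_forest <- function(forest, clean = TRUE, cleaning = cleaning_config(),
                           partition_resolution = c("hourly", "native"),
                           period_rule = c("growth", "time"),
                           period_trim = 0.05,
                           probability_denominator = c("per_hour_of_day", "all_hours"),
                           filters = list(min_sites = 1L, min_years = 1L)) {
  partition_resolution <- match.arg(partition_resolution)
  cleaned <- if (clean) lapply(forest$dendro, clean_series, cfg = cleaning)
             else forest$dendro
  hourly <- lapply(cleaned, to_hourly)
  partitions <- if (partition_resolution == "hourly")
    lapply(hourly, zg_partition)
  else lapply(cleaned, function(s) partition_to_hourly(zg_partition(s)))

  res <- analyze_partitions(partitions, forest$env, forest$meta,
                            period_rule = period_rule,
                            period_trim = period_trim,
                            probability_denominator = probability_denominator,
                            filters = filters)
  report <- forest$report %||% run_report()
  report <- report_stage(report, "analyze",
                         list(series = length(forest$dendro),
                              kept_tree_years = nrow(res$filters$kept),
                              dropped_tree_years = nrow(res$filters$dropped),
                              species = nrow(res$summary)))
  report$tallies <- res$filters$tally
  c(list(cleaned = cleaned, hourly = hourly, partitions = partitions,
         report = report), res)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the defaults listed in Details.
#' @details Keys: `synthetic` ([synthetic_config()] for the simulate stage),
#'   `clean` (logical), `cleaning` ([cleaning_config()]),
#'   `partition_resolution`, `period_rule`, `period_trim`,
#'   `probability_denominator`, `filters` (list),
#'   `grid_axes`, `grid_span`, `grid_degree`, `bootstrap_B`,
#'   `envelope_vpd_max`, `envelope_swp_min`, `seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(synthetic = NULL, clean = TRUE,
                   cleaning = cleaning_config(),
                   partition_resolution = "hourly", period_rule = "growth",
                   period_trim = 0.05,
                   probability_denominator = "per_hour_of_day",
                   filters = list(min_sites = 1L, min_years = 1L),
                   grid_axes = c("vpd_kpa", "swp_kpa"),
                   grid_span = 0.75, grid_degree = 2, bootstrap_B = 1000L,
                   envelope_vpd_max = 0.4, envelope_swp_min = -900,
                   seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0)
    stop_dd("pipeline_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(defaults, class = "pipeline_config")
}

need_file <- function(out, name, stage) {
  path <- file.path(out, name)
  if (!file.exists(path))
    stop_dd("run_pipeline '%s': missing required file %s (run the upstream stage first)",
            stage, path)
  path
}

downstream_inputs <- function(out, stage) {
  list(partitions = read_partition_csv(need_file(out, "partition.csv", stage)),
       env = read_env_csv(need_file(out, "env.csv", stage)),
       meta = read_meta_csv(need_file(out, "meta.csv", stage)))
}

run_analysis_stage <- function(out, stage, config) {
  inp <- downstream_inputs(out, stage)
  analyze_partitions(inp$partitions, inp$env, inp$meta,
                     period_rule = config$period_rule,
                     period_trim = config$period_trim,
                     probability_denominator = config$probability_denominator,
                     filters = config$filters)
}

#' Run pipeline stages against a working directory
#'
#' Orchestrates the stages as materialized-CSV steps so any stage can be
#' re-run and inspected independently: `simulate` writes the synthetic input
#' bundle (`dendro.csv`, `env.csv`, `meta.csv`, `truth.csv`); `clean` writes
#' `cleaned.csv`; `partition` writes the hourly zero-growth partition
#' (`partition.csv`); `periods` the growth periods; `diel` the filtered diel
#' profiles (`profiles.csv`); `response` the VPD x SWP response grid with
#' bootstrap CoV (`grid.csv`) plus envelope and condition curves; `summary`
#' the species summary and peak-timing fits; `all` chains everything.
#' Downstream stages read the partition CSV -- a missing upstream file is an
#' error naming it. Every invocation rewrites `report.json`. Outputs are
#' pure functions of (inputs, config, seed).
#'
#' @param subcommand One of `"simulate"`, `"clean"`, `"partition"`,
#'   `"periods"`, `"diel"`, `"response"`, `"summary"`, `"all"`.
#' @param out Working/output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(subcommand, out, config = pipeline_config()) {
  subcommand <- match.arg(subcommand,
    c("simulate", "clean", "partition", "periods", "diel", "response",
      "summary", "all"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- run_report(config = list(subcommand = subcommand,
                                     partition_resolution = config$partition_resolution,
                                     period_rule = config$period_rule,
                                     filters = config$filters),
                       seed = config$seed)
  written <- character(0)

  if (subcommand == "simulate") {
    cfg <- config$synthetic %||% synthetic_config(seed = config$seed)
    generate_forest(cfg, dir = out)
    return(invisible(file.path(out, c("dendro.csv", "env.csv", "meta.csv",
                                      "truth.csv", "report.json"))))
  }

  if (subcommand %in% c("clean", "all")) {
    raw <- read_radius_csv(need_file(out, "dendro.csv", subcommand))
    cleaned <- if (config$clean) lapply(raw, clean_series, cfg = config$cleaning)
               else raw
    write_radius_csv(cleaned, file.path(out, "cleaned.csv"))
    written <- c(written, file.path(out, "cleaned.csv"))
    report <- report_stage(report, "clean",
                           list(series = length(cleaned),
                                rows = sum(vapply(cleaned, nrow, 0L))))
    if (subcommand == "clean") {
      write_run_report(report, file.path(out, "report.json"))
      return(invisible(c(written, file.path(out, "report.json"))))
    }
  }

  if (subcommand %in% c("partition", "all")) {
    src <- file.path(out, "cleaned.csv")
    if (!file.exists(src)) src <- need_file(out, "dendro.csv", subcommand)
    series <- read_radius_csv(src)
    partitions <- if (config$partition_resolution == "hourly")
      lapply(series, function(s) zg_partition(to_hourly(s)))
    else lapply(series, function(s) partition_to_hourly(zg_partition(s)))
    write_partition_csv(partitions, file.path(out, "partition.csv"))
    written <- c(written, file.path(out, "partition.csv"))
    report <- report_stage(report, "partition",
                           list(series = length(partitions),
                                growth_hours = sum(vapply(partitions, function(p)
                                  sum(p$is_growth_hour), 0L))))
    if (subcommand == "partition") {
      write_run_report(report, file.path(out, "report.json"))
      return(invisible(c(written, file.path(out, "report.json"))))
    }
  }

  res <- run_analysis_stage(out, subcommand, config)
  report <- report_stage(report, "analyze",
                         list(kept_tree_years = nrow(res$filters$kept),
                              dropped_tree_years = nrow(res$filters$dropped),
                              species = nrow(res$summary)))
  report$tallies <- res$filters$tally

  if (subcommand %in% c("periods", "all")) {
    write_table_csv(as.data.frame(res$periods), file.path(out, "periods.csv"))
    write_table_csv(attr(res$periods, "coverage"),
                    file.path(out, "periods_coverage.csv"))
    written <- c(written, file.path(out, c("periods.csv", "periods_coverage.csv")))
  }
  if (subcommand %in% c("diel", "all")) {
    write_profile_csv(c(res$profiles, res$agg$site_species, res$agg$species,
                        list(pooled = res$agg$pooled)),
                      file.path(out, "profiles.csv"))
    written <- c(written, file.path(out, "profiles.csv"))
  }
  if (subcommand %in% c("response", "all")) {
    grid <- response_surface(res$joined, axes = config$grid_axes,
                             span = config$grid_span,
                             degree = config$grid_degree)
    nu <- nrow(attr(grid, "unit_matrix"))
    if (nu >= 2L)
      grid <- bootstrap_cov(grid, B = config$bootstrap_B, seed = config$seed)
    write_grid_csv(grid, file.path(out, "grid.csv"))
    write_table_csv(median_condition_curves(res$joined),
                    file.path(out, "condition_curves.csv"))
    report <- report_stage(report, "response",
                           list(envelope_pct =
                                  growth_envelope(res$joined,
                                                  config$envelope_vpd_max,
                                                  config$envelope_swp_min),
                                variance_captured =
                                  attr(grid, "variance_captured") %||% NA,
                                resampling_units = nu))
    written <- c(written, file.path(out, c("grid.csv", "condition_curves.csv")))
  }
  if (subcommand %in% c("summary", "all")) {
    write_table_csv(res$summary, file.path(out, "summary.csv"))
    if (nrow(res$summary) >= 3L &&
        length(unique(res$summary$time_gro_max)) > 1L) {
      f1 <- regress_peak_time(res$summary, "h_gro_yr")
      f2 <- regress_peak_time(res$summary, "gro_yr")
      report <- report_stage(report, "cross_species",
        list(h_gro_yr_slope = f1$slope, h_gro_yr_adj_r2 = f1$adj_r2,
             gro_yr_slope = f2$slope, gro_yr_adj_r2 = f2$adj_r2))
    }
    written <- c(written, file.path(out, "summary.csv"))
  }
  write_run_report(report, file.path(out, "report.json"))
  invisible(c(written, file.path(out, "report.json")))
}
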