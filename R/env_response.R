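#' Join hourly growth partitions with environmental series
#'
#' Builds the hourly analysis table behind the response surfaces, envelopes
#' and condition curves: one row per tree per hour inside the tree's
#' site x species x year growth period, with the site's VPD and SWP attached.
#'
#' @param partitions Named list of hourly `growth_partition` objects.
#' @param env Named list of [env_series()] (names = site_id).
#' @param meta A [tree_meta()] table.
#' @param periods Output of [detect_growth_periods()].
#' @return A data frame with columns `series_id`, `site_id`, `species`,
#'   `year`, `timestamp`, `hour`, `gro_inc_um`, `is_growth_hour`, `vpd_kpa`,
#'   `swp_kpa`.
#' @export
join_growth_env <- function(partitions, env, meta, periods) {
  rows <- list()
  for (sid in names(partitions)) {
    m <- meta[meta$series_id == sid, , drop = FALSE]
    e <- env[[m$site_id]]
    if (is.null(e)) stop_dd("join_growth_env: no env series for site '%s'", m$site_id)
    p <- partitions[[sid]]
    per <- periods[periods$site_id == m$site_id & periods$species == m$species, , drop = FALSE]
    for (i in seq_len(nrow(per))) {
      sel <- p$timestamp >= per$start[i] & p$timestamp <= per$end[i] &
             year_of(p$timestamp) == per$year[i]
      if (!any(sel)) next
      sub <- p[sel, ]
      ei <- match(as.numeric(sub$timestamp), as.numeric(e$timestamp))
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sid, site_id = m$site_id, species = m$species,
        year = per$year[i], timestamp = sub$timestamp,
        hour = hour_of(sub$timestamp),
        gro_inc_um = sub$gro_inc_um, is_growth_hour = sub$is_growth_hour,
        vpd_kpa = e$vpd_kpa[ei], swp_kpa = e$swp_kpa[ei],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop_dd("join_growth_env: empty join")
  do.call(rbind, rows)
}

#' Multiple linear regression of a diel growth profile on covariates
#'
#' Ordinary least squares of the 24 hour-of-day growth values on the named
#' 24-value covariate series, with all pairwise interaction terms when
#' `interactions = TRUE`. Reports R^2 and adjusted R^2
#' (adj R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)).
#'
#' @param growth24 Numeric vector of 24 diel growth values.
#' @param covariates Named list (or data frame) of numeric 24-value series.
#' @param interactions Include all pairwise products of covariates.
#' @return A list of class `regression_result` with `coefficients`, `r2`,
#'   `adj_r2`, `n`, `p`.
#' @export
regress_diel <- function(growth24, covariates, interactions = FALSE) {
  df <- data.frame(growth = growth24, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  form <- if (interactions && ncol(df) > 2)
    stats::as.formula(paste("growth ~ (", paste(names(df)[-1], collapse = " + "), ")^2"))
  else stats::as.formula(paste("growth ~", paste(names(df)[-1], collapse = " + ")))
  fit <- stats::lm(form, data = df)
  p <- length(stats::coef(fit)) - 1L
  if (nrow(df) < p + 2L)
    stop_dd("regress_diel: %d non-missing bins for %d covariates (need >= p + 2)",
            nrow(df), p)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_dd("regress_diel: collinear design; collapsed covariate(s): %s",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  s <- summary(fit)
  r2 <- s$r.squared; adj <- s$adj.r.squared
  if (stats::var(df$growth) == 0) r2 <- adj <- 0  # constant response explains nothing
  structure(list(response = "growth", covariates = names(df)[-1],
                 coefficients = cf, r2 = r2,
                 adj_r2 = adj, n = nrow(df), p = p, fit = fit),
            class = "regression_result")
}

cut_cells <- function(x, breaks) {
  i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
  list(index = i, mid = mid, k = length(breaks) - 1L)
}

#' Binned and loess-smoothed growth response surface
#'
#' Bins the relative hourly growth contribution onto a two-dimensional grid
#' over environmental axes (or hour-of-day x environment), respecting the
#' nested design: per tree-year, the growth in each cell is normalized to the
#' tree-year's total (so each tree-year distributes 100%), tree-years are
#' averaged per tree, trees per site x species unit, and the surface is the
#' mean over units -- so unmasked cell values sum to 100 before smoothing.
#' Cells with no observed hours at all are masked ("no data"). A local
#' polynomial (loess) smoother over the unmasked cells provides the
#' interpolated surface; the fraction of binned variance it captures is
#' reported so the span can be tuned.
#'
#' @param joined Output of [join_growth_env()].
#' @param axes Character(2): any of `"vpd_kpa"`, `"swp_kpa"`, `"hour"`.
#' @param breaks1,breaks2 Bin boundaries for the two axes. Defaults: VPD
#'   0.05-kPa bins over \[0, 1.5\]; SWP 50-kPa bins over \[-1000, 0\]; hours
#'   0..23. Observations outside the range fall into the edge bins.
#' @param span,degree loess parameters (defaults 0.75, 2).
#' @return A data frame of class `env_response_grid` with columns `axis1`,
#'   `axis2` (bin centres), `value_pct`, `smoothed_pct`, `n`, `masked`;
#'   attributes `unit_matrix` (site x species units by cells, for
#'   [bootstrap_cov()]), `variance_captured`, `axes`.
#' @export
response_surface <- function(joined, axes = c("vpd_kpa", "swp_kpa"),
                             breaks1 = NULL, breaks2 = NULL,
                             span = 0.75, degree = 2) {
  stopifnot(length(axes) == 2, all(axes %in% c("vpd_kpa", "swp_kpa", "hour")))
  if (nrow(joined) == 0L) stop_dd("response_surface: empty join")
  default_breaks <- list(vpd_kpa = seq(0, 1.5, by = 0.05),
                         swp_kpa = seq(-1000, 0, by = 50),
                         hour = seq(-0.5, 23.5, by = 1))
  breaks1 <- breaks1 %||% default_breaks[[axes[1]]]
  breaks2 <- breaks2 %||% default_breaks[[axes[2]]]
  c1 <- cut_cells(joined[[axes[1]]], breaks1)
  c2 <- cut_cells(joined[[axes[2]]], breaks2)
  ncell <- c1$k * c2$k
  cell <- (c2$index - 1L) * c1$k + c1$index

  ok <- !is.na(cell)
  jk <- joined[ok, ]; cellk <- cell[ok]

  # per tree-year normalized cell mass, averaged up the hierarchy
  ty <- paste(jk$series_id, jk$year, sep = "@")
  ty_mass <- lapply(split(seq_len(nrow(jk)), ty), function(ix) {
    tot <- sum(jk$gro_inc_um[ix])
    v <- numeric(ncell)
    if (tot > 0) {
      agg <- tapply(jk$gro_inc_um[ix], cellk[ix], sum)
      v[as.integer(names(agg))] <- 100 * agg / tot
    }
    v
  })
  ty_tab <- jk[match(names(ty_mass), paste(jk$series_id, jk$year, sep = "@")),
               c("series_id", "site_id", "species")]
  tree_mass <- lapply(split(names(ty_mass), ty_tab$series_id), function(nms)
    rowMeans(do.call(cbind, ty_mass[nms])))
  tree_unit <- vapply(names(tree_mass), function(s) {
    i <- match(s, jk$series_id); paste(jk$site_id[i], jk$species[i], sep = ":")
  }, "")
  unit_mass <- t(vapply(split(names(tree_mass), tree_unit), function(nms)
    rowMeans(do.call(cbind, tree_mass[nms])), numeric(ncell)))
  unit_mass <- unit_mass[order(rownames(unit_mass)), , drop = FALSE]

  value <- colMeans(unit_mass)
  n_obs <- tabulate(cellk, nbins = ncell)
  masked <- n_obs == 0L

  grid <- data.frame(axis1 = rep(c1$mid, times = c2$k),
                     axis2 = rep(c2$mid, each = c1$k),
                     value_pct = value, n = n_obs, masked = masked)
  grid$value_pct[masked] <- NA_real_

  # loess over unmasked cells
  um <- grid[!masked, ]
  grid$smoothed_pct <- NA_real_
  variance_captured <- NA_real_
  if (nrow(um) >= 10) {
    fit <- stats::loess(value_pct ~ axis1 + axis2, data = um, span = span,
                        degree = degree,
                        control = stats::loess.control(surface = "direct"))
    sm <- pmax(stats::predict(fit, um), 0)
    grid$smoothed_pct[!masked] <- sm
    ss_tot <- sum((um$value_pct - mean(um$value_pct))^2)
    if (ss_tot > 0)
      variance_captured <- 1 - sum((um$value_pct - sm)^2) / ss_tot
  }
  structure(grid, axes = axes, unit_matrix = unit_mass,
            variance_captured = variance_captured,
            breaks = list(breaks1, breaks2), span = span, degree = degree,
            class = c("env_response_grid", "data.frame"))
}

#' Bootstrap coefficient of variation per grid cell
#'
#' Resamples the site x species units behind a response surface with
#' replacement `B` times, recomputes every cell, and reports the coefficient
#' of variation CoV = 100 sd/mean per cell with a quality class: very good
#' (CoV < 10), good (10 to < 20), satisfactory (20-50), poor (> 50). Cells
#' whose bootstrap mean is 0 are classed poor. Units are ordered by name
#' before resampling, so the result is invariant to input unit order and
#' reproducible under a fixed seed.
#'
#' @param grid An `env_response_grid` from [response_surface()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling (RNG state is restored).
#' @return The grid with `cov` and `quality_class` columns added.
#' @export
bootstrap_cov <- function(grid, B = 1000L, seed = 1L) {
  if (B < 2L) stop_dd("bootstrap_cov: B must be >= 2")
  M <- attr(grid, "unit_matrix")
  if (!is.null(rownames(M))) M <- M[order(rownames(M)), , drop = FALSE]
  n <- nrow(M)
  if (n < 2L) stop_dd("bootstrap_cov: need >= 2 resampling units, have %d", n)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  boots <- matrix(0, B, ncol(M))
  for (b in seq_len(B))
    boots[b, ] <- colMeans(M[sample.int(n, n, replace = TRUE), , drop = FALSE])
  mu <- colMeans(boots)
  sdv <- apply(boots, 2, stats::sd)
  cov <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  cov[grid$masked] <- NA_real_
  grid$cov <- cov
  grid$quality_class <- cov_quality_class(cov)
  grid$quality_class[!grid$masked & (is.na(cov))] <- "poor"
  grid$quality_class[grid$masked] <- NA_character_
  grid
}

#' Quality class of a bootstrap coefficient of variation
#'
#' Class boundaries: very_good \[0, 10), good \[10, 20), satisfactory
#' \[20, 50\], poor (50, Inf); undefined CoV (zero mean) is poor.
#'
#' @param cov Numeric CoV values (percent).
#' @return Character vector of classes.
#' @export
cov_quality_class <- function(cov) {
  out <- rep("poor", length(cov))
  out[!is.na(cov) & cov < 50 + 1e-12] <- "satisfactory"
  out[!is.na(cov) & cov < 20] <- "good"
  out[!is.na(cov) & cov < 10] <- "very_good"
  out[is.na(cov)] <- "poor"
  out
}

#' Fraction of total growth inside a VPD x SWP envelope
#'
#' Percentage of all growth increments occurring in hours with
#' `VPD < vpd_max` and `SWP > swp_min` -- the "main growth" envelope.
#' Monotonically non-decreasing in `vpd_max` and non-increasing in `swp_min`.
#'
#' @param joined Output of [join_growth_env()].
#' @param vpd_max Upper VPD bound, kPa (default 0.4).
#' @param swp_min Lower SWP bound, kPa (default -900).
#' @return Fraction in percent.
#' @export
growth_envelope <- function(joined, vpd_max = 0.4, swp_min = -900) {
  tot <- sum(joined$gro_inc_um)
  if (tot <= 0) stop_dd("growth_envelope: zero total growth")
  inside <- !is.na(joined$vpd_kpa) & !is.na(joined$swp_kpa) &
            joined$vpd_kpa < vpd_max & joined$swp_kpa > swp_min
  100 * sum(joined$gro_inc_um[inside]) / tot
}

#' Smallest VPD bound capturing a target growth fraction
#'
#' At a fixed SWP bound, the smallest `vpd_max` such that
#' [growth_envelope()] reaches `target_fraction` of total growth.
#'
#' @param joined Output of [join_growth_env()].
#' @param target_fraction Target fraction of total growth (0-1, default 0.75).
#' @param swp_min Fixed lower SWP bound, kPa.
#' @return VPD threshold in kPa, or `NA` (with a warning) when unreachable.
#' @export
vpd_threshold_for_fraction <- function(joined, target_fraction = 0.75,
                                       swp_min = -900) {
  tot <- sum(joined$gro_inc_um)
  sel <- !is.na(joined$vpd_kpa) & !is.na(joined$swp_kpa) &
         joined$swp_kpa > swp_min & joined$gro_inc_um > 0
  d <- joined[sel, c("vpd_kpa", "gro_inc_um")]
  d <- d[order(d$vpd_kpa), ]
  frac <- cumsum(d$gro_inc_um) / tot
  i <- which(frac >= target_fraction)[1]
  if (is.na(i)) {
    warn_dd("vpd_threshold_for_fraction: %.0f%% of growth not reachable at SWP > %g",
            100 * target_fraction, swp_min)
    return(NA_real_)
  }
  # smallest open bound strictly above the crossing observation
  d$vpd_kpa[i] + 1e-9
}

#' Median diel VPD and SWP conditions, all hours vs growth hours
#'
#' For each hour-of-day, the median (with 25%/75% quantiles) VPD and SWP over
#' all growth-period hours (`subset = "all"`) and over growth hours only
#' (`subset = "growth"`). Hours-of-day without growth hours yield missing
#' values, not zeros.
#'
#' @param joined Output of [join_growth_env()].
#' @return A long data frame: `hour`, `subset`, and median/q25/q75 of
#'   `vpd_kpa` and `swp_kpa`.
#' @export
median_condition_curves <- function(joined) {
  one <- function(d, hours = 0:23) {
    do.call(rbind, lapply(hours, function(h) {
      x <- d[d$hour == h, ]
      if (nrow(x) == 0L)
        return(data.frame(hour = h, vpd_median = NA_real_, vpd_q25 = NA_real_,
                          vpd_q75 = NA_real_, swp_median = NA_real_,
                          swp_q25 = NA_real_, swp_q75 = NA_real_))
      data.frame(hour = h,
                 vpd_median = stats::median(x$vpd_kpa, na.rm = TRUE),
                 vpd_q25 = q25(x$vpd_kpa), vpd_q75 = q75(x$vpd_kpa),
                 swp_median = stats::median(x$swp_kpa, na.rm = TRUE),
                 swp_q25 = q25(x$swp_kpa), swp_q75 = q75(x$swp_kpa))
    }))
  }
  all_h <- one(joined)
  gro_h <- one(joined[joined$is_growth_hour, ])
  all_h$subset <- "all"; gro_h$subset <- "growth"
  rbind(all_h, gro_h)
}
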