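# Builds an hourly partition whose increment at hour-of-day (k-1) %% 24 is
# inc[k]: a baseline point one hour before May 1 makes the first increment
# land on May 1 00:00.
partition_from_hourly_inc <- function(inc, id = "T1") {
  zg_partition(hourly_series(c(0, cumsum(inc)), id = id,
                             start = "2020-04-30 23:00:00"))
}

period_for <- function(p, site = "S1", species = "SPA", year = 2020) {
  data.frame(site_id = site, species = species, year = year,
             start = p$timestamp[1], end = tail(p$timestamp, 1))
}

test_that("hour-of-day contributions are normalized to 100", {
  # growth only at hour 3 over 10 days
  inc <- rep(0, 240)
  inc[4 + 24 * (0:9)] <- 2
  p <- partition_from_hourly_inc(inc)
  prof <- tree_diel_profile(p, period_for(p))
  expect_equal(prof$contribution_pct[prof$hour == 3], 100)
  expect_equal(sum(prof$contribution_pct), 100, tolerance = 1e-9)

  # uniform growth: every bin 100/24
  pu <- partition_from_hourly_inc(rep(1, 240))
  pr <- tree_diel_profile(pu, period_for(pu))
  expect_equal(pr$contribution_pct, rep(100 / 24, 24), tolerance = 1e-6)
})

test_that("growth probability counts growth hours per hour-of-day", {
  # 10 days; growth at hour 3 on 4 of them
  inc <- rep(0, 240)
  inc[4 + 24 * (0:3)] <- 1
  p <- partition_from_hourly_inc(inc)
  prof <- tree_diel_profile(p, period_for(p))
  expect_equal(prof$probability_pct[prof$hour == 3], 40)
  expect_equal(prof$probability_pct[prof$hour == 5], 0)
  # the alternative denominator spreads total period hours evenly
  prof2 <- tree_diel_profile(p, period_for(p),
                             probability_denominator = "all_hours")
  expect_equal(prof2$probability_pct[prof2$hour == 3],
               100 * 4 / (241 / 24), tolerance = 1e-6)
})

test_that("hourly growth rates are medians over growth hours only", {
  inc <- rep(0, 240)
  inc[4 + 24 * (0:4)] <- c(1, 2, 3, 4, 10)
  p <- partition_from_hourly_inc(inc)
  prof <- tree_diel_profile(p, period_for(p))
  expect_equal(prof$rate_um_h[prof$hour == 3], 3)
  expect_true(is.na(prof$rate_um_h[prof$hour == 7]))
})

test_that("aggregation follows mean-within-site then median-across-units", {
  mkprof <- function(share0, id) {
    inc <- rep(c(share0, rep((100 - share0) / 23, 23)), 10)
    p <- partition_from_hourly_inc(inc, id)
    tree_diel_profile(p, period_for(p))
  }
  # three sites, one tree each; bin-0 contributions 2, 4, 9 percent
  profs <- list(T1 = mkprof(2, "T1"), T2 = mkprof(4, "T2"),
                T3 = mkprof(9, "T3"))
  meta <- tree_meta(c("T1", "T2", "T3"), c("a", "b", "c"),
                    rep("SPA", 3), c("S1", "S2", "S3"))
  agg <- aggregate_profiles(profs, meta)
  sp <- agg$species[["SPA"]]
  expect_equal(sp$contribution_pct[sp$hour == 0], 4, tolerance = 1e-6)
  expect_equal(sp$contribution_pct_q25[sp$hour == 0], 3, tolerance = 1e-6)
  expect_equal(sp$contribution_pct_q75[sp$hour == 0], 6.5, tolerance = 1e-6)
  expect_equal(attr(sp, "n_units"), 3L)
  # single tree at a single site: species profile equals the tree profile
  agg1 <- aggregate_profiles(profs["T1"], meta)
  expect_equal(agg1$species[["SPA"]]$contribution_pct,
               profs$T1$contribution_pct)
})

test_that("aggregation is invariant to tree and site order", {
  res <- two_site_analysis()
  meta <- generate_forest(synthetic_config(seed = 11, n_sites = 2))$meta
  a1 <- aggregate_profiles(res$profiles, meta)
  a2 <- aggregate_profiles(rev(res$profiles), meta)
  expect_equal(a1$pooled$contribution_pct, a2$pooled$contribution_pct)
  expect_equal(a1$species[[1]]$contribution_pct_q75,
               a2$species[[1]]$contribution_pct_q75)
})

test_that("pooled median of an even number of units is the central midpoint", {
  df <- function(v, id) {
    d <- data.frame(hour = 0:23, contribution_pct = v,
                    probability_pct = v, rate_um_h = v)
    structure(d, level = "tree", id = id, n_units = 1L,
              class = c("diel_profile", "data.frame"))
  }
  units <- list(T1 = df(rep(1, 24), "T1"), T2 = df(rep(2, 24), "T2"),
                T3 = df(rep(4, 24), "T3"), T4 = df(rep(8, 24), "T4"))
  meta <- tree_meta(paste0("T", 1:4), paste0("t", 1:4), rep("SPA", 4),
                    paste0("S", 1:4))
  agg <- aggregate_profiles(units, meta)
  expect_equal(agg$pooled$contribution_pct, rep(3, 24))
})

test_that("peak timing takes argmax/argmin with earliest-hour tie-break", {
  mk <- function(v) structure(data.frame(hour = 0:23, contribution_pct = v),
                              class = c("diel_profile", "data.frame"))
  v <- rep(1, 24); v[2] <- 10; v[14] <- 0.1
  pk <- peak_timing(mk(v))
  expect_equal(pk$time_gro_max, 1L)
  expect_equal(pk$time_gro_min, 13L)
  vt <- c(5, 5, rep(4, 22))
  expect_equal(peak_timing(mk(vt))$time_gro_max, 0L)
  expect_warning(pk0 <- peak_timing(mk(rep(2, 24))), "degenerate")
  expect_equal(pk0$time_gro_max, 0L)
})

test_that("multi-year trees average their yearly contribution vectors", {
  inc1 <- rep(0, 240); inc1[4 + 24 * (0:9)] <- 1      # 2020: all at hour 3
  inc2 <- rep(0, 240); inc2[6 + 24 * (0:9)] <- 1      # 2021: all at hour 5
  r1 <- c(0, cumsum(inc1)); r2 <- c(0, cumsum(inc2))
  s <- radius_series("T1", c(hour_seq(241, "2020-04-30 23:00:00"),
                             hour_seq(241, "2021-04-30 23:00:00")),
                     c(r1, max(r1) + r2))
  p <- zg_partition(s)
  periods <- rbind(
    data.frame(site_id = "S1", species = "SPA", year = 2020,
               start = s$timestamp[1], end = s$timestamp[241]),
    data.frame(site_id = "S1", species = "SPA", year = 2021,
               start = s$timestamp[242], end = s$timestamp[482]))
  prof <- tree_diel_profile(p, periods)
  expect_equal(prof$contribution_pct[prof$hour == 3], 50)
  expect_equal(prof$contribution_pct[prof$hour == 5], 50)
  expect_equal(sum(prof$contribution_pct), 100, tolerance = 1e-9)
})

test_that("zero-growth tree-years are rejected by the profile step", {
  p <- zg_partition(hourly_series(rep(100, 240),
                                  start = "2020-05-01 00:00:00"))
  expect_error(tree_diel_profile(p, period_for(p)), "zero annual growth")
})
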