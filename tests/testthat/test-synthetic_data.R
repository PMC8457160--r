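test_that("weather generation is deterministic under a seed", {
  cfg <- synthetic_config(seed = 4)
  e1 <- simulate_weather(cfg, "S1", seed = 4)
  e2 <- simulate_weather(cfg, "S1", seed = 4)
  expect_identical(e1, e2)
  e3 <- simulate_weather(cfg, "S1", seed = 5)
  expect_false(identical(e1$temp_c, e3$temp_c))
})

test_that("continuous rain forces VPD near zero and wet soil", {
  cfg <- synthetic_config(seed = 4, weather = list(
    rain_prob = 1, rain_start = c(0, 0.01), rain_dur = c(24, 24.01),
    rain_rh_dip = 0))
  e <- simulate_weather(cfg, "S1", seed = 4)
  expect_true(all(e$vpd_kpa <= 0.1))
  expect_true(all(e$swp_kpa >= -50))
})

test_that("without rain the soil-water bucket only draws down", {
  cfg <- synthetic_config(seed = 4, weather = list(rain_prob = 0))
  e <- simulate_weather(cfg, "S1", seed = 4)
  daily <- e$swp_kpa[!duplicated(format(e$timestamp, "%Y-%m-%d"), fromLast = TRUE)]
  expect_true(all(diff(daily) <= 1e-12))
  expect_true(all(e$swp_kpa >= -1500))
})

test_that("environmental series stay in physical ranges", {
  e <- simulate_weather(synthetic_config(seed = 12), "S1", seed = 12)
  expect_true(all(e$relh_pct >= 0 & e$relh_pct <= 100))
  expect_true(all(e$vpd_kpa >= 0))
  expect_true(all(e$swp_kpa <= 0))
  expect_equal(nrow(e), 24 * 366)  # 2020 is a leap year
})

test_that("an unconstrained tree is a noisy ramp whose total is recovered", {
  cfg <- synthetic_config(seed = 4)
  env <- simulate_weather(cfg, "S1", seed = 4)
  spec <- species_spec("RAMP", shrink_coeff = 0, vpd_threshold = 999,
                       swp_threshold = -99999, season = c(1, 366))
  sim <- simulate_tree(env, spec, "T1", seed = 4, noise_sd = 0.2)
  expect_true(all(sim$truth$true_gro_inc_um == spec$growth_rate))
  p <- zg_partition(sim$series)
  total_true <- sum(sim$truth$true_gro_inc_um)
  n <- nrow(sim$series)
  expect_lt(abs(tail(p$gro_cum_um, 1) - total_true), 3 * 0.2 * sqrt(log(n)))
})

test_that("a zero-rate tree accumulates only noise-level growth", {
  cfg <- synthetic_config(seed = 4)
  env <- simulate_weather(cfg, "S1", seed = 4)
  spec <- species_spec("NULL0", growth_rate = 0)
  sim <- simulate_tree(env, spec, "T1", seed = 4, noise_sd = 0.2)
  expect_true(all(sim$truth$true_gro_inc_um == 0))
  p <- zg_partition(sim$series)
  # bounded by the expected maximum of the noise around the water signal
  expect_lt(tail(p$gro_cum_um, 1), 4 * 0.2 * sqrt(2 * log(nrow(sim$series))))
})

test_that("emitted radius minus the true state is Gaussian at the set sd", {
  cfg <- synthetic_config(seed = 4)
  env <- simulate_weather(cfg, "S1", seed = 4)
  spec <- species_spec("SPA")
  sim <- simulate_tree(env, spec, "T1", seed = 4, noise_sd = 0.2)
  tr <- sim$truth
  n <- nrow(env)
  state <- c(0, cumsum(tr$true_gro_inc_um)) +
    c(tr$true_water_um, tail(tr$true_water_um, 1))
  # reconstruct the 10-min interpolation and difference it out
  base <- rep(seq_len(n), each = 6); frac <- rep(0:5, n) / 6
  clean <- state[base] * (1 - frac) + state[pmin(base + 1, n + 1)] * frac
  # the final boundary state is not stored in the truth; drop the last hour
  resid <- (sim$series$value_um - clean)[seq_len(6 * (n - 1))]
  expect_lt(abs(mean(resid)), 0.01)
  expect_equal(sd(resid), 0.2, tolerance = 0.05)
  expect_lt(abs(stats::quantile(resid, 0.975) - stats::qnorm(0.975, 0, 0.2)),
            0.05)
})

test_that("injected spikes and shifts are recorded in the truth flags", {
  cfg <- synthetic_config(seed = 4)
  env <- simulate_weather(cfg, "S1", seed = 4)
  spec <- species_spec("SPA")
  sim <- simulate_tree(env, spec, "T1", seed = 4, noise_sd = 0.2,
                       outlier_prob = 2e-4, shift_prob = 2e-5)
  expect_gt(length(attr(sim$truth, "outlier_idx")), 0L)
  # the cleaner removes the spikes it injected
  cleaned <- clean_series(sim$series)
  big <- abs(diff(cleaned$value_um)) > 150
  expect_equal(sum(big), 0L)
})

test_that("forest generation is reproducible and bookkeeps every hour", {
  cfg <- synthetic_config(seed = 5, n_sites = 2, trees_per_site = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_forest(cfg, dir = d1)
  f2 <- generate_forest(cfg, dir = d2)
  expect_length(f1$dendro, 4L)
  expect_length(f1$env, 2L)
  expect_equal(nrow(f1$truth), 2 * 2 * 24 * 366)
  for (nm in c("dendro.csv", "env.csv", "meta.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, nm)), readLines(file.path(d2, nm)))
  # truth timestamps match the emitted hourly grid per tree
  expect_identical(unique(f1$truth$series_id), f1$meta$series_id)
})

test_that("true increments respect the configured gates", {
  f <- default_forest()
  env <- f$env[["S01"]]
  tr <- f$truth[f$truth$series_id == "S01-T01", ]
  i <- match(as.numeric(tr$timestamp), as.numeric(env$timestamp))
  grow <- tr$true_gro_inc_um > 0
  expect_true(all(env$vpd_kpa[i][grow] < 0.4))
  expect_true(all(env$swp_kpa[i][grow] > -900))
  doy <- as.POSIXlt(tr$timestamp)$yday + 1
  expect_true(all(doy[grow] >= 110 & doy[grow] <= 280))
  expect_true(all(tr$true_water_um[grow] > -0.5))
})

test_that("growth-hour counts are recovered from noise-free series", {
  f0 <- generate_forest(synthetic_config(seed = 1, noise_sd = 0))
  p10 <- lapply(f0$dendro, function(s) partition_to_hourly(zg_partition(s)))
  measured <- sum(vapply(p10, function(p) sum(p$is_growth_hour), 0L))
  truth <- sum(f0$truth$true_gro_inc_um > 0)
  expect_lt(abs(measured - truth) / truth, 0.10)
})

test_that("a slow-rehydration species shifts its diel window later", {
  f <- two_species_forest()
  tr <- f$truth
  peak_of <- function(sid) {
    t1 <- tr[tr$series_id == sid, ]
    hod <- as.POSIXlt(t1$timestamp)$hour
    as.integer(names(which.max(tapply(t1$true_gro_inc_um, hod, sum))))
  }
  expect_gte(peak_of("S01-T02") - peak_of("S01-T01"), 2L)
})
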