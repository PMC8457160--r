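# builds an hourly partition whose cumulative growth follows `inc` (um/h)
partition_from_inc <- function(inc, id = "T1", start = "2020-05-01 00:00:00") {
  zg_partition(hourly_series(cumsum(c(0, inc)), id = id, start = start))
}

test_that("uniform growth gives 5% and 95% crossings at the right days", {
  # 100 um spread uniformly over May 1-10 (10 um/day)
  inc <- rep(100 / 240, 240)
  p <- partition_from_inc(inc)
  rec <- detect_growth_period(list(T1 = p), "S1", "SPA", 2020)
  expect_s3_class(rec, "growth_period")
  expect_identical(format(rec$start, "%Y-%m-%d"), "2020-05-01")
  expect_identical(format(rec$end, "%Y-%m-%d"), "2020-05-10")
  # crossings near 5% and 95% of the 240-h span
  span_h <- as.numeric(rec$end - rec$start, units = "hours")
  expect_gt(span_h, 0.85 * 240)
  expect_lt(span_h, 0.95 * 240)
})

test_that("all growth in a single hour yields a degenerate one-hour period", {
  inc <- rep(0, 48); inc[20] <- 50
  p <- partition_from_inc(inc)
  rec <- detect_growth_period(list(T1 = p), "S1", "SPA", 2020)
  expect_equal(rec$start, rec$end)
})

test_that("the period of two staggered trees comes from the averaged curve", {
  # equal totals, one growing May 1-10, one May 11-20
  inc1 <- c(rep(0.5, 240), rep(0, 240))
  inc2 <- c(rep(0, 240), rep(0.5, 240))
  p1 <- partition_from_inc(inc1, "T1")
  p2 <- partition_from_inc(inc2, "T2")
  rec <- detect_growth_period(list(T1 = p1, T2 = p2), "S1", "SPA", 2020)
  # the averaged curve reaches 5% when tree 1 reaches 10% (about hour 24)
  # and 95% when tree 2 reaches 90% (about hour 456)
  expect_gte(as.numeric(rec$start), as.numeric(p1$timestamp[1]))
  expect_true(format(rec$start, "%d") %in% c("01", "02"))
  expect_true(format(rec$end, "%d") %in% c("19", "20"))
  # strictly inside the union of the two windows
  expect_gt(as.numeric(rec$end) - as.numeric(rec$start), 0)
  expect_lt(as.numeric(rec$end), as.numeric(tail(p2$timestamp, 1)))
})

test_that("zero-growth groups yield no period", {
  p <- partition_from_inc(rep(0, 48))
  expect_null(detect_growth_period(list(T1 = p), "S1", "SPA", 2020))
})

test_that("trimming keeps 90% of annual growth on the averaged curve", {
  set.seed(13)
  inc <- rexp(2000) * rbinom(2000, 1, 0.3)
  p <- partition_from_inc(inc)
  rec <- detect_growth_period(list(T1 = p), "S1", "SPA", 2020)
  sel <- p$timestamp >= rec$start & p$timestamp <= rec$end
  frac <- sum(p$gro_inc_um[sel]) / sum(p$gro_inc_um)
  expect_gte(frac, 0.90)
  expect_lte(frac, 1.0)
})

test_that("the calendar-time rule trims 5% of the duration at each end", {
  inc <- rep(0, 1000); inc[100:900] <- 1
  p <- partition_from_inc(inc)
  rec_g <- detect_growth_period(list(T1 = p), "S1", "SPA", 2020, rule = "growth")
  rec_t <- detect_growth_period(list(T1 = p), "S1", "SPA", 2020, rule = "time")
  dur <- as.numeric(rec_t$end - rec_t$start, units = "hours")
  expect_equal(dur, 0.9 * 801, tolerance = 0.01)
  # for uniform growth both rules agree closely
  expect_lt(abs(as.numeric(rec_g$start - rec_t$start, units = "hours")), 2)
})

test_that("inclusion filters drop the documented violations with reasons", {
  start <- "2020-05-01 00:00:00"
  mk <- function(total, hours = 400, id) {
    inc <- rep(0, 2000); inc[seq_len(hours)] <- total / hours
    partition_from_inc(inc, id, start)
  }
  parts <- list(A = mk(500, id = "A"), B = mk(80, id = "B"),
                C = mk(500, id = "C"), D = mk(500, id = "D"))
  # C's record stops halfway through its growth window: low period coverage
  parts$C <- parts$C[seq_len(200), ]
  class(parts$C) <- c("growth_partition", "data.frame")
  meta <- tree_meta(c("A", "B", "C", "D"), c("a", "b", "c", "d"),
                    rep("SPA", 4), rep("S1", 4))
  periods <- detect_growth_periods(parts, meta)
  filt <- apply_inclusion_filters(meta, parts, periods,
                                  min_sites = 1L, min_years = 1L)
  expect_setequal(filt$kept$series_id, c("A", "D"))
  expect_equal(filt$tally$min_annual_growth, 1L)
  expect_equal(filt$tally$coverage, 1L)
  expect_true(any(grepl("min_annual_growth", filt$dropped$reasons)))
  expect_true(any(grepl("coverage", filt$dropped$reasons)))

  # with the paper's network thresholds everything at one site one year drops
  filt2 <- apply_inclusion_filters(meta, parts, periods)
  expect_equal(nrow(filt2$kept), 0L)
  expect_gte(filt2$tally$species_sites, 4L)
})

test_that("filters are order-independent (single simultaneous evaluation)", {
  start <- "2020-05-01 00:00:00"
  mk <- function(total, id) {
    inc <- rep(0, 1000); inc[1:200] <- total / 200
    partition_from_inc(inc, id, start)
  }
  parts <- list(A = mk(500, "A"), B = mk(50, "B"))
  meta <- tree_meta(c("A", "B"), c("a", "b"), c("SPA", "SPA"), c("S1", "S1"))
  periods <- detect_growth_periods(parts, meta)
  f1 <- apply_inclusion_filters(meta, parts, periods, min_sites = 1L,
                                min_years = 1L, min_trees_per_site = 2L)
  # B fails min growth; the site still counts 2 individuals (census on the
  # unfiltered table), so A survives regardless of evaluation order
  expect_identical(f1$kept$series_id, "A")
})
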