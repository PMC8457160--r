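joined_stub <- function(gro, vpd, swp, hour = NULL, growth = gro > 0) {
  n <- length(gro)
  if (is.null(hour)) hour <- (seq_len(n) - 1) %% 24
  data.frame(series_id = "T1", site_id = "S1", species = "SPA", year = 2020,
             timestamp = hour_seq(n), hour = hour,
             gro_inc_um = gro, is_growth_hour = growth,
             vpd_kpa = vpd, swp_kpa = swp)
}

test_that("diel regression recovers exact and noisy linear structure", {
  vpd <- 0.6 + 0.5 * cos(2 * pi * (0:23 - 14) / 24)
  fit <- suppressWarnings(regress_diel(10 - 5 * vpd, list(vpd = vpd)))
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)
  expect_equal(unname(fit$coefficients["vpd"]), -5)

  fit0 <- suppressWarnings(regress_diel(rep(4, 24), list(vpd = vpd)))
  expect_equal(fit0$r2, 0)

  set.seed(2)
  fitn <- regress_diel(2 + 3 * vpd + rnorm(24, 0, 0.01), list(vpd = vpd))
  expect_gt(fitn$adj_r2, 0.9)
})

test_that("collinear covariates raise an error naming the collapsed term", {
  vpd <- 0.6 + 0.5 * cos(2 * pi * (0:23 - 14) / 24)
  expect_error(regress_diel(1:24, list(vpd = vpd, vpd2 = 2 * vpd)),
               "collinear.*vpd2")
})

test_that("interaction models include pairwise products", {
  x1 <- (0:23) / 23; x2 <- cos(2 * pi * (0:23) / 24)
  y <- 1 + x1 + x2 + 2 * x1 * x2
  fit <- suppressWarnings(regress_diel(y, list(a = x1, b = x2), interactions = TRUE))
  expect_equal(fit$r2, 1)
  expect_true("a:b" %in% names(fit$coefficients))
})

test_that("response surface bins mass that sums to 100 before smoothing", {
  # all growth at one (VPD, SWP) cell
  j <- joined_stub(gro = c(rep(2, 10), rep(0, 50)),
                   vpd = c(rep(0.12, 10), runif(50, 0.5, 1.4)),
                   swp = c(rep(-120, 10), runif(50, -950, -500)))
  g <- response_surface(j)
  expect_equal(sum(g$value_pct, na.rm = TRUE), 100, tolerance = 1e-9)
  top <- g[which.max(g$value_pct), ]
  expect_equal(top$value_pct, 100)
  expect_equal(top$axis1, 0.125); expect_equal(top$axis2, -125)
  expect_true(all(g$masked | g$n > 0))
  expect_true(all(is.na(g$value_pct[g$masked])))

  # growth uniform over 4 populated cells: 25% each
  j2 <- joined_stub(gro = rep(1, 4), vpd = c(0.02, 0.02, 0.32, 0.32),
                    swp = c(-20, -620, -20, -620))
  g2 <- response_surface(j2)
  expect_equal(sort(g2$value_pct[!g2$masked]), rep(25, 4))
})

test_that("surface respects the nested design when units differ", {
  # two site-species units with all growth in different cells: the surface
  # averages units (50/50), not raw observations
  j <- rbind(joined_stub(rep(1, 8), rep(0.1, 8), rep(-100, 8)),
             within(joined_stub(rep(3, 4), rep(0.7, 4), rep(-100, 4)), {
               series_id <- "T2"; site_id <- "S2"
             }))
  g <- response_surface(j)
  expect_equal(sort(g$value_pct[!g$masked & g$value_pct > 0]), c(50, 50))
  expect_equal(nrow(attr(g, "unit_matrix")), 2L)
})

test_that("bootstrap CoV is zero for identical units and classed very_good", {
  res <- two_site_analysis()
  g <- response_surface(res$joined)
  M <- attr(g, "unit_matrix")
  gid <- g
  attr(gid, "unit_matrix") <- M[c(1, 1), ]
  b <- bootstrap_cov(gid, B = 200, seed = 5)
  nonzero <- !gid$masked & !is.na(b$cov)
  expect_true(all(abs(b$cov[nonzero]) < 1e-12))
  expect_true(all(b$quality_class[nonzero] == "very_good"))
})

test_that("bootstrap CoV is reproducible and invariant to unit order", {
  res <- two_site_analysis()
  g <- response_surface(res$joined)
  b1 <- bootstrap_cov(g, B = 300, seed = 9)
  b2 <- bootstrap_cov(g, B = 300, seed = 9)
  expect_identical(b1$cov, b2$cov)
  gswap <- g
  attr(gswap, "unit_matrix") <- attr(g, "unit_matrix")[c(2, 1), ]
  b3 <- bootstrap_cov(gswap, B = 300, seed = 9)
  expect_identical(b1$cov, b3$cov)
  expect_error(bootstrap_cov(g, B = 1), "B must be")
})

test_that("quality classes follow the stated CoV boundaries", {
  expect_identical(cov_quality_class(c(0, 9.99, 10, 15, 19.99, 20, 50, 50.01, 120, NA)),
                   c("very_good", "very_good", "good", "good", "good",
                     "satisfactory", "satisfactory", "poor", "poor", "poor"))
})

test_that("the growth envelope fraction matches direct accounting", {
  j <- joined_stub(gro = c(5, 5), vpd = c(0.2, 0.2), swp = c(-100, -100))
  expect_equal(growth_envelope(j, 0.4, -900), 100)
  j2 <- joined_stub(gro = c(5, 5), vpd = c(0.3, 0.8), swp = c(-100, -100))
  expect_equal(growth_envelope(j2, 0.4, -900), 50)
})

test_that("the envelope is monotone in its bounds", {
  set.seed(14)
  j <- joined_stub(gro = rexp(200), vpd = runif(200, 0, 1.4),
                   swp = -runif(200, 0, 1000))
  vmax <- seq(0.1, 1.4, by = 0.1)
  fr_v <- vapply(vmax, function(v) growth_envelope(j, v, -900), 0)
  expect_true(all(diff(fr_v) >= 0))
  smin <- seq(-900, -100, by = 100)
  fr_s <- vapply(smin, function(s) growth_envelope(j, 0.4, s), 0)
  expect_true(all(diff(fr_s) <= 0))
})

test_that("the conditional VPD threshold captures the target fraction", {
  j <- joined_stub(gro = rep(1, 100), vpd = seq(0.01, 1, length.out = 100),
                   swp = rep(-100, 100))
  thr <- vpd_threshold_for_fraction(j, target_fraction = 0.75, swp_min = -900)
  expect_equal(growth_envelope(j, thr, -900), 75)
  # unreachable when the SWP bound excludes the growth
  expect_warning(
    thr2 <- vpd_threshold_for_fraction(j, 0.75, swp_min = -50), "not reachable")
  expect_true(is.na(thr2))
})

test_that("median condition curves split all hours vs growth hours", {
  # VPD alternates 0/1; growth only when VPD = 0
  n <- 48
  vpd <- rep(c(0, 1), n / 2)
  j <- joined_stub(gro = ifelse(vpd == 0, 1, 0), vpd = vpd,
                   swp = rep(-100, n), hour = rep(c(3, 3), n / 2))
  mc <- median_condition_curves(j)
  all3 <- mc[mc$subset == "all" & mc$hour == 3, ]
  gro3 <- mc[mc$subset == "growth" & mc$hour == 3, ]
  expect_equal(all3$vpd_median, 0.5)
  expect_equal(gro3$vpd_median, 0)
  # hour-of-day without growth hours: missing, not zero
  gro5 <- mc[mc$subset == "growth" & mc$hour == 5, ]
  expect_true(is.na(gro5$vpd_median))
})

test_that("loess smoothing reports the captured variance fraction", {
  res <- two_site_analysis()
  g <- response_surface(res$joined)
  vc <- attr(g, "variance_captured")
  expect_true(is.finite(vc))
  expect_lte(vc, 1)
  expect_true(all(g$smoothed_pct[!g$masked] >= 0))
})
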