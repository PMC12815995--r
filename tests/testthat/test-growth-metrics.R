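# Regional growth rates and the percent growth modulation statistic.

test_that("label distance converts to growth rate by the interval", {
  expect_equal(growth_rate_from_labels(2.4, 13), 2400 / 13)
  expect_equal(growth_rate_from_labels(0, 13), 0)
  expect_error(growth_rate_from_labels(2.6, 0), "positive")
  expect_error(growth_rate_from_labels(-1, 13), "non-negative")
})

test_that("regionalize reproduces a flat profile in every region", {
  reg <- regionalize(flat_profile(178))
  expect_equal(unname(reg$per_region_mean), rep(178, 3))
  expect_equal(reg$whole_physis_mean, 178)
  expect_equal(unname(reg$n_stations), c(10, 20, 10))
})

test_that("regional means agree with dense quadrature of a smooth profile", {
  g <- function(x) 150 + 40 * sin(pi * x / 30) + 15 * cos(2.3 * x / 30)
  n <- 20000
  x <- (seq_len(n) - 0.5) / n * 30
  p <- physis_profile(x, g(x), ap_width_mm = 30)
  reg <- regionalize(p)
  for (k in 1:3) {
    lims <- list(c(0, 7.5), c(7.5, 22.5), c(22.5, 30))[[k]]
    oracle <- integrate(g, lims[1], lims[2], rel.tol = 1e-10)$value / diff(lims)
    expect_equal(unname(reg$per_region_mean[k]), oracle, tolerance = 1e-6)
  }
  oracle_whole <- integrate(g, 0, 30, rel.tol = 1e-10)$value / 30
  expect_equal(reg$whole_physis_mean, oracle_whole, tolerance = 1e-6)
})

test_that("regional means are insensitive to station density for smooth profiles", {
  for (n in c(40, 80)) {
    p <- gen_growth_profile(178, 53, n_stations = n)
    assign(paste0("r", n), regionalize(p)$per_region_mean)
  }
  expect_equal(unname(get("r40")), unname(get("r80")), tolerance = 0.01)
})

test_that("whole-physis mean is the station mean, not the mean of region means", {
  x <- (1:40 - 0.5) * 0.75
  p <- physis_profile(x, 50 + 100 * (x / 30)^2, ap_width_mm = 30)
  reg <- regionalize(p)
  expect_equal(reg$whole_physis_mean, mean(p$growth_rate))
  expect_false(isTRUE(all.equal(reg$whole_physis_mean, mean(reg$per_region_mean))))
})

test_that("a region without stations raises an error", {
  p <- physis_profile(c(10, 20, 25, 29), c(1, 2, 3, 4) * 100, ap_width_mm = 30)
  expect_error(regionalize(p), "no stations")
})

test_that("percent growth modulation follows its defining formula", {
  gm <- growth_modulation(174, 191, 178)
  expect_equal(gm$gm_percent, 100 * (174 - 191) / 178)
  expect_equal(growth_modulation(150, 150, 150)$gm_percent, 0)
  expect_error(growth_modulation(174, 191, 0), "positive")
})

test_that("the statistic is antisymmetric and scale invariant", {
  set.seed(42)
  for (i in 1:20) {
    rates <- runif(40, 50, 250)
    p <- physis_profile((1:40 - 0.5) * 0.75, rates, ap_width_mm = 30)
    gm <- growth_modulation_profile(p)
    swapped <- physis_profile((1:40 - 0.5) * 0.75, rev(rates), ap_width_mm = 30)
    expect_equal(growth_modulation_profile(swapped)$gm_percent, -gm$gm_percent,
                 tolerance = 1e-12)
    lambda <- runif(1, 0.1, 5)
    scaled <- physis_profile((1:40 - 0.5) * 0.75, lambda * rates, ap_width_mm = 30)
    expect_equal(growth_modulation_profile(scaled)$gm_percent, gm$gm_percent,
                 tolerance = 1e-9)
  }
})

test_that("anterior unossified stations are reported when requested", {
  p <- modulated_profile()
  reg <- regionalize(p, unossified_fraction = 0.1)
  # the anterior-most stations carry more modulation than the anterior quarter
  expect_gt(reg$anterior_unossified_mean, reg$per_region_mean[["anterior"]])
})

test_that("tethered-space rates are elementwise sums and demand a common scheme", {
  a <- regionalize(flat_profile(90))
  b <- regionalize(flat_profile(88))
  ts <- tethered_space(a, b)
  expect_equal(unname(ts$per_region_mean), rep(178, 3))
  expect_equal(ts$whole_physis_mean, 178)
  expect_identical(tethered_space(a, b)$per_region_mean,
                   tethered_space(b, a)$per_region_mean)
  z <- regionalize(flat_profile(0 + 1e-12))
  expect_lt(tethered_space(z, z)$whole_physis_mean, 1e-11)
  expect_error(tethered_space(a, regionalize(flat_profile(88), scheme_halves())),
               "different region schemes")
})

test_that("coarser outer regions dilute peripherally localized modulation", {
  p <- modulated_profile(gm = 40, loc = 0.2)
  tab <- region_scheme_sensitivity(p)
  gm <- setNames(tab$gm_percent, tab$scheme)
  expect_true(abs(gm["quarters"]) >= abs(gm["thirds"]))
  expect_true(abs(gm["thirds"]) >= abs(gm["halves"]))
  flat <- region_scheme_sensitivity(flat_profile())
  expect_equal(flat$gm_percent, rep(0, nrow(flat)))
  single <- region_scheme_sensitivity(p, list(quarters = scheme_quarters()))
  expect_equal(single$gm_percent, growth_modulation_profile(p)$gm_percent)
})

test_that("cohort comparison matches the pooled-variance Student t oracle", {
  # hand formula: t = (mA - mB) / sqrt(sp2 * (1/nA + 1/nB))
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  res <- cohort_compare(1:3, 4:6)
  expect_equal(res$t, pooled_t(1:3, 4:6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  set.seed(8)
  a <- rnorm(6, 10, 2); b <- rnorm(9, 12, 3)
  expect_equal(cohort_compare(a, b)$t, pooled_t(a, b))
  same <- cohort_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("degenerate zero-variance comparisons are handled explicitly", {
  pr <- cohort_compare(c(5, 6, 7), c(4, 5, 6), paired = TRUE)
  expect_equal(pr$p, 0)
  expect_true(is.infinite(pr$t) && pr$t > 0)
  expect_equal(cohort_compare(c(5, 6), c(5, 6), paired = TRUE)$p, 1)
  expect_error(cohort_compare(1, 1:3), "at least two")
  expect_error(cohort_compare(1:3, 1:4, paired = TRUE), "equal group sizes")
})
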