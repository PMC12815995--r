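# Synthetic cohort generator: deterministic inversion, unit consistency,
# seed determinism, and noiseless parameter recovery.

test_that("zero-modulation profile is flat at the base rate", {
  p <- gen_growth_profile(178, 0, 0.25, 40)
  expect_equal(p$growth_rate, rep(178, 40))
  expect_equal(growth_modulation_profile(p)$gm_percent, 0)
})

test_that("profile inversion realizes the modulation target and mean exactly", {
  for (gm in c(-18, -1, 10, 14, 53)) {
    p <- gen_growth_profile(178, gm, 0.25, 40)
    got <- growth_modulation_profile(p)
    expect_equal(got$gm_percent, gm, tolerance = 1e-12)
    expect_equal(mean(p$growth_rate), 178, tolerance = 1e-12)
  }
})

test_that("modulation is confined to the peripheral localization fraction", {
  p <- gen_growth_profile(178, 53, localization = 0.25, n_stations = 40)
  central <- p$positions / p$ap_width_mm >= 0.25 & p$positions / p$ap_width_mm < 0.75
  expect_true(all(abs(p$growth_rate[central] - p$growth_rate[which(central)[1]]) < 1e-9))
})

test_that("unrealizable modulation targets raise an error", {
  expect_error(gen_growth_profile(100, 400, 0.25, 40), "non-negative")
  expect_error(gen_growth_profile(100, -400, 0.25, 40), "non-negative")
})

test_that("label distances and growth rates are linked by the interval", {
  p <- gen_growth_profile(150, 20, interval_days = 14)
  expect_equal(1000 * p$label_distance / 14, p$growth_rate, tolerance = 1e-12)
})

test_that("all-zero-variance animal has every station at the cohort mean", {
  spec <- cohort_spec("degenerate", 1, 178, 0, 0, 0, measurement_noise_sd = 0,
                      seed = 1)
  an <- gen_cohort(spec)$animals[[1]]
  for (ph in an$physes) expect_equal(ph$growth_rate, rep(178, 40))
})

test_that("cohorts are reproducible under a fixed seed and vary across seeds", {
  spec <- cohort_spec("seeded", 3, 178, 21, 53, 43, seed = 11)
  a <- quiet_gen(gen_cohort(spec))
  b <- quiet_gen(gen_cohort(spec))
  expect_identical(a$animals, b$animals)
  spec$seed <- 12
  c3 <- quiet_gen(gen_cohort(spec))
  expect_false(identical(a$animals[[1]]$physes[[1]]$growth_rate,
                         c3$animals[[1]]$physes[[1]]$growth_rate))
})

test_that("extreme but realizable latent draws use the asymmetric fallback
           exactly", {
  spec <- cohort_spec("wide", 1, 100, 0, 150, 0, measurement_noise_sd = 0,
                      seed = 3)
  an <- gen_cohort(spec)$animals[[1]]   # no clamping expected
  expect_true(all(an$physes[[1]]$growth_rate >= 0))
  got <- growth_modulation_profile(an$physes[[1]])
  expect_equal(got$gm_percent, 150, tolerance = 1e-9)
  expect_equal(got$total_mean_rate, 100, tolerance = 1e-9)
})

test_that("infeasible latent draws are clamped with a classed warning and
           the stored latent truth matches the clamped profile", {
  spec <- cohort_spec("extreme", 1, 100, 0, 500, 0, measurement_noise_sd = 0,
                      seed = 3)
  expect_warning(an <- gen_cohort(spec)$animals[[1]],
                 class = "vertegrow_clamp_warning")
  expect_true(all(an$physes[[1]]$growth_rate >= 0))
  # realized latent is below the nominal target but exactly recoverable
  expect_lt(an$latent$gm_percent, 500)
  got <- growth_modulation_profile(an$physes[[1]])
  expect_equal(got$gm_percent, an$latent$gm_percent, tolerance = 1e-9)
})

test_that("noiseless pipeline recovery is exact for every animal", {
  for (gm in c(-11, 0, 53)) {
    co <- gen_cohort(noiseless_spec(gm = gm, seed = 5))
    res <- analyze_growth(co)
    expect_equal(res$per_animal$gm_percent, rep(gm, 2), tolerance = 1e-9)
    expect_equal(res$per_animal$mean_rate, rep(178, 2), tolerance = 1e-9)
  }
})

test_that("noisy cohort estimates recover the stored latent truth", {
  spec <- cohort_spec("noisy", 30, 178, 21, 14, 11, measurement_noise_sd = 10,
                      seed = 21)
  co <- quiet_gen(gen_cohort(spec))
  res <- analyze_growth(co)
  latent_gm <- vapply(co$animals, function(a) a$latent$gm_percent, numeric(1))
  # per-animal estimates average physis noise; compare animal by animal
  expect_equal(res$per_animal$gm_percent[order(res$per_animal$animal_id)],
               latent_gm[order(vapply(co$animals, `[[`, "", "id"))],
               tolerance = 0.15)
})

test_that("Cobb series are piecewise-linear and reach the untreated endpoint", {
  const <- gen_cobb_series(44.2, 0, 0, 90)
  expect_equal(const$cobb_deg, rep(44.2, nrow(const)))
  two_phase <- gen_cobb_series(40, c(2, 4), 0, 28, dt_days = 7)
  expect_equal(two_phase$cobb_deg, c(40, 42, 44, 48, 52))
  untreated <- gen_cobb_series(44.2, 2.5, 0, 90)
  expect_equal(untreated$cobb_deg[untreated$day == 84], 44.2 + 2.5 * 12)
})

test_that("pressure draws are clamped non-negative and seed-stable", {
  expect_equal(gen_pressures(77, 0, 5), rep(77, 5))
  a <- gen_pressures(100, 10, 8, seed = 4)
  b <- gen_pressures(100, 10, 8, seed = 4)
  expect_identical(a, b)
  expect_true(all(gen_pressures(1, 50, 200, seed = 9) >= 0))
})
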