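# Stress-modulated growth law and the longitudinal tethering simulator.

test_that("growth law hits its anchor points and is continuous at arrest", {
  law <- growth_law_params(g0 = 178)
  expect_equal(growth_rate_at_stress(law, -0.15), 178)
  expect_equal(growth_rate_at_stress(law, -0.5), 0)
  expect_equal(growth_rate_at_stress(law, -0.7), 0)
  expect_equal(growth_rate_at_stress(law, -0.325), 89)  # midpoint linearity
  eps <- 1e-9
  expect_lt(growth_rate_at_stress(law, -0.5 + eps), 1e-5)
})

test_that("growth law is monotone non-decreasing in stress", {
  law <- growth_law_params(g0 = 100)
  sig <- seq(-1, 0.5, by = 0.01)
  g <- growth_rate_at_stress(law, sig)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g[sig <= -0.5] == 0))
  expect_gt(growth_rate_at_stress(law, 0.1), 100)  # tension accelerates
})

test_that("uniform homeostatic stress predicts zero modulation", {
  flat <- flat_profile(178)
  pred <- predict_modulation_from_stress(rep(-0.15, 40), profile = flat,
                                         baseline_profile = flat)
  expect_equal(pred$modulation$gm_percent, 0)
  expect_equal(pred$growth_rate, rep(178, 40))
})

test_that("flexible correction predicts positive modulation, stiff predicts arrest", {
  seg <- motion_segment()
  params <- growth_law_params(g0 = 178)
  fl <- predict_modulation_from_stress(realign(seg, 10, "flexible"), params)
  expect_gt(fl$modulation$gm_percent, 0)
  expect_false(any(fl$arrested))
  stf <- predict_modulation_from_stress(realign(seg, 10, "stiff"), params)
  expect_gt(sum(stf$arrested), 0)
  expect_true(all(stf$growth_rate[stf$arrested] == 0))
})

test_that("predicted modulation grows with the stress gradient (affine profiles)", {
  flat <- flat_profile(100)
  x <- flat$positions
  gms <- vapply(c(0.1, 0.2, 0.3), function(slope) {
    sigma <- -0.15 - slope * (x - 15) / 15  # anterior tension, posterior compression
    params <- growth_law_params(g0 = 100)
    pred <- predict_modulation_from_stress(sigma, params, profile = flat)
    # brute-force stationwise oracle
    oracle_g <- pmax(0, 100 * (1 + params$beta * (sigma - params$sigma_hom)))
    oracle_g[sigma <= -0.5] <- 0
    expect_equal(pred$growth_rate, oracle_g)
    pred$modulation$gm_percent
  }, numeric(1))
  expect_true(all(diff(gms) > 0))
})

test_that("a single step conserves added height and leaves wedges unchanged
           under symmetric growth", {
  cfg <- sim_config("untreated", baseline_gm = 0, baseline_rate = 65,
                    duration_days = 10)
  s0 <- spine_state(cfg)
  stepped <- step_spine(s0, cfg)
  s1 <- stepped$state
  expect_equal(s1$vert_wedge, s0$vert_wedge)       # symmetric growth
  expect_equal(s1$disc_wedge, s0$disc_wedge)       # no tether
  expect_equal(s1$cum_height_mm, rep(2 * 65 / 1000, cfg$n_levels))
  expect_equal(cobb_angle(s1), cobb_angle(s0))
})

test_that("anterior-favoring growth corrects the kyphotic wedge monotonically", {
  cfg <- sim_config("untreated", baseline_gm = +20, baseline_rate = 100,
                    duration_days = 20)
  tr <- simulate_tethering(cfg)$trajectory
  expect_true(all(diff(tr$cobb_deg) < 0))
})

test_that("untreated simulation with the observed asymmetry progresses
           monotonically from the starting deformity", {
  cfg <- sim_config("untreated")
  tr <- simulate_tethering(cfg)$trajectory
  expect_equal(tr$cobb_deg[1], 44.2, tolerance = 1e-9)
  expect_true(all(diff(tr$cobb_deg) > 0))
  expect_true(all(tr$tether_force_N == 0))
})

test_that("tether tension produces emergent biphasic growth modulation", {
  tr <- run_cohort_trajectories(list(low_tension = sim_config("low_tension"),
                                     high_tension = sim_config("high_tension")))
  lo <- tr[tr$scenario == "low_tension", ]
  hi <- tr[tr$scenario == "high_tension", ]
  early <- function(d) (d$cobb_deg[d$day == 14] - d$cobb_deg[d$day == 0]) / 14
  late <- function(d) (d$cobb_deg[d$day == 28] - d$cobb_deg[d$day == 14]) / 14
  # early phase: high tension corrects faster
  expect_lt(early(hi), early(lo))
  # late phase: near-equal correction rates (load independence)
  expect_lt(abs(late(hi) - late(lo)), 0.25 * max(abs(late(hi)), abs(late(lo))))
  # high-tension cable force decays as correction proceeds
  expect_lt(hi$tether_force_N[hi$day == 14], hi$tether_force_N[hi$day == 0])
  # instantaneous modulation difference shrinks (load-dependent -> independent)
  gap <- hi$gm_percent - lo$gm_percent
  expect_lt(abs(gap[length(gap)]), abs(gap[2]))
})

test_that("simulator is insensitive to halving the time step", {
  a <- simulate_tethering(sim_config("high_tension", dt_days = 1,
                                     duration_days = 14))$trajectory
  b <- simulate_tethering(sim_config("high_tension", dt_days = 0.5,
                                     duration_days = 14))$trajectory
  expect_equal(a$cobb_deg[a$day == 14], b$cobb_deg[b$day == 14], tolerance = 0.05)
})
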