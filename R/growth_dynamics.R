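# Stress-modulated growth law (linear, with an arrest threshold) and a
# longitudinal explicit-Euler simulator of Cobb-angle trajectories under
# posterior tethering.

#' Parameters of the stress-modulated growth law
#'
#' Linear growth-rate sensitivity to growth-plate axial stress: the physis
#' grows at `g0` at the homeostatic stress, faster under tension, slower
#' under compression, and arrests (rate 0) at and beyond `sigma_arrest` MPa
#' of compression. The default slope `beta = 1/(sigma_arrest + sigma_hom
#' magnitude)` makes the linear law reach zero exactly at the arrest
#' threshold, so the law is continuous there.
#'
#' @param g0 Baseline physeal growth rate at homeostatic stress, um/day.
#' @param sigma_hom Homeostatic stress, MPa (default -0.15, the baseline
#'   swelling-pressurized state).
#' @param beta Sensitivity, MPa^-1 (> 0).
#' @param sigma_arrest Compressive stress magnitude at which growth arrests,
#'   MPa (default 0.5).
#' @return Object of class `growth_law_params`.
#' @export
growth_law_params <- function(g0 = 178, sigma_hom = -0.15, beta = NULL,
                              sigma_arrest = 0.5) {
  if (is.null(beta)) beta <- 1 / (sigma_arrest + sigma_hom)
  stopifnot(g0 > 0, beta > 0, sigma_arrest > 0, sigma_hom > -sigma_arrest)
  structure(list(g0 = g0, sigma_hom = sigma_hom, beta = beta,
                 sigma_arrest = sigma_arrest), class = "growth_law_params")
}

#' Growth rate under a given growth-plate stress
#'
#' `g = max(0, g0 * (1 + beta * (sigma - sigma_hom)))`, with a hard override
#' `g = 0` whenever `sigma <= -sigma_arrest` regardless of the slope.
#' Vectorized over `sigma` (tension positive, MPa).
#'
#' @param params A [growth_law_params()].
#' @param sigma Stress(es), MPa.
#' @return Growth rate(s), um/day.
#' @export
growth_rate_at_stress <- function(params, sigma) {
  stopifnot(inherits(params, "growth_law_params"), all(is.finite(sigma)))
  g <- pmax(0, params$g0 * (1 + params$beta * (sigma - params$sigma_hom)))
  g[sigma <= -params$sigma_arrest] <- 0
  g
}

# Stationwise modulation of a baseline rate field by the stress profile:
# each station's own baseline rate plays the role of g0.
modulated_rates <- function(baseline_rates, params, sigma) {
  g <- pmax(0, baseline_rates * (1 + params$beta * (sigma - params$sigma_hom)))
  g[sigma <= -params$sigma_arrest] <- 0
  g
}

#' Predicted growth modulation from a growth-plate stress profile
#'
#' Applies the stress-modulated growth law station by station to a
#' realignment stress profile, then computes regional rates and the percent
#' growth modulation statistic of the predicted growth field.
#'
#' @param state A [realign()] result (its `sigma_gp` profile and station grid
#'   are used), or a numeric stress vector if `profile` is supplied.
#' @param params A [growth_law_params()].
#' @param scheme A [region_scheme()].
#' @param baseline_profile Optional [physis_profile()] of baseline rates on
#'   the same station grid; by default the baseline is uniform at
#'   `params$g0`.
#' @param profile Station grid carrier when `state` is a bare numeric vector.
#' @return List with `modulation` (a `growth_modulation_result`), `profile`
#'   (the predicted growth [physis_profile()]), `growth_rate`, and
#'   `arrested` (logical per station).
#' @export
predict_modulation_from_stress <- function(state, params = growth_law_params(),
                                           scheme = scheme_quarters(),
                                           baseline_profile = NULL,
                                           profile = NULL) {
  if (inherits(state, "realignment_state")) {
    sigma <- state$sigma_gp
    x <- state$stations
    width <- state$segment$width
  } else {
    stopifnot(is.numeric(state), inherits(profile, "physis_profile"))
    sigma <- state
    x <- profile$positions
    width <- profile$ap_width_mm
    if (length(sigma) != length(x)) stop("stress profile and station grid differ in length")
  }
  base <- if (is.null(baseline_profile)) rep(params$g0, length(sigma))
          else {
            if (length(baseline_profile$growth_rate) != length(sigma)) {
              stop("baseline profile is not on the stress station grid")
            }
            baseline_profile$growth_rate
          }
  g <- modulated_rates(base, params, sigma)
  pred <- physis_profile(x, g, ap_width_mm = width)
  list(modulation = growth_modulation_profile(pred, scheme),
       profile = pred, growth_rate = g,
       arrested = sigma <= -params$sigma_arrest)
}

#' Longitudinal simulation configuration
#'
#' Scenario presets: `untreated` (no construct, baseline growth asymmetry of
#' -10 percent GM at 65 um/day, 90 days), `low_tension` (5 N pretension) and
#' `high_tension` (25.6 N pretension), both tethered arms at 178 um/day over
#' 28 days. The initial deformity is `n_levels` identical units of
#' `disc_wedge0 + vert_wedge0` degrees (defaults give a 44.2 degree Cobb over
#' four levels).
#'
#' @param scenario "untreated", "low_tension" or "high_tension".
#' @param dt_days Euler time step, days.
#' @param duration_days Simulated follow-up, days.
#' @param n_levels Number of simulated motion-segment units.
#' @param segment A [motion_segment()].
#' @param construct A [tether_construct()]; built from the scenario
#'   pretension when NULL.
#' @param params A [growth_law_params()]; scenario baseline rate when NULL.
#' @param baseline_gm Latent percent growth modulation of the untethered
#'   growth field (negative: posterior outgrows anterior, progressive
#'   kyphosis).
#' @param baseline_rate Whole-physis baseline rate, um/day; scenario default
#'   when NULL.
#' @param localization Peripheral localization of the baseline asymmetry.
#' @param creep_tau_days Time constant of disc creep toward the elastic
#'   equilibrium correction, days.
#' @param relax_tau_days Time constant of disc stress relaxation (the rest
#'   wedge drifting toward the held correction), days.
#' @param axis Axis regime for the mechanics (see [axis_position()]).
#' @param disc_wedge0,vert_wedge0 Initial disc and vertebral wedge per level,
#'   degrees.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("untreated", "low_tension", "high_tension"),
                       dt_days = 1, duration_days = NULL, n_levels = 4,
                       segment = motion_segment(), construct = NULL,
                       params = NULL, baseline_gm = -10, baseline_rate = NULL,
                       localization = 0.25, creep_tau_days = 4,
                       relax_tau_days = 7, axis = "flexible",
                       disc_wedge0 = 10, vert_wedge0 = 1.05) {
  scenario <- match.arg(scenario)
  tethered <- scenario != "untreated"
  if (is.null(duration_days)) duration_days <- if (tethered) 28 else 90
  stopifnot(dt_days > 0, duration_days >= dt_days, n_levels >= 1)
  if (is.null(baseline_rate)) baseline_rate <- if (tethered) 178 else 65
  if (is.null(params)) params <- growth_law_params(g0 = baseline_rate)
  if (is.null(construct) && tethered) {
    construct <- tether_construct(pretension = switch(scenario,
                                                      low_tension = 5,
                                                      high_tension = 25.6))
  }
  baseline_profile <- gen_growth_profile(baseline_rate, baseline_gm,
                                         localization, segment$n_stations,
                                         segment$width)
  structure(list(scenario = scenario, tethered = tethered, dt = dt_days,
                 duration = duration_days, n_levels = as.integer(n_levels),
                 segment = segment, construct = construct, params = params,
                 baseline_profile = baseline_profile,
                 creep_tau = creep_tau_days, relax_tau = relax_tau_days,
                 axis = axis, disc_wedge0 = disc_wedge0,
                 vert_wedge0 = vert_wedge0), class = "sim_config")
}

#' Initial spine state for a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Object of class `spine_state`: per-level current disc wedge, disc
#'   rest wedge, vertebral wedge, cable force, plus growth bookkeeping.
#' @export
spine_state <- function(config) {
  n <- config$n_levels
  F0 <- if (config$tethered) config$construct$pretension else 0
  structure(list(
    day = 0,
    disc_wedge = rep(config$disc_wedge0, n),
    rest_wedge = rep(config$disc_wedge0, n),
    vert_wedge = rep(config$vert_wedge0, n),
    force = rep(F0, n),
    cum_height_mm = rep(0, n)
  ), class = "spine_state")
}

#' Cobb angle over the instrumented span
#'
#' Sum of the disc and vertebral wedge angles of all simulated levels
#' (measurements within the construct only, to stay clear of junctional
#' effects outside it).
#'
#' @param state A [spine_state()].
#' @return Cobb angle, degrees (kyphosis positive).
#' @export
cobb_angle <- function(state) sum(state$disc_wedge) + sum(state$vert_wedge)

#' Advance the spine state by one time step
#'
#' Per level and per step: (1) solve the elastic equilibrium correction for
#' the current cable force; (2) creep the disc wedge toward it; (3) relax the
#' disc rest wedge toward the held shape (stress relaxation); (4) evaluate
#' the growth-plate stress at the current elastic deflection and the
#' stress-modulated growth field; (5) grow both physes, updating the
#' vertebral wedge by atan((dh_post - dh_ant)/width); (6) update the cable
#' force from the construct stretch, F <- max(0, F + k * dpath), where the
#' path shortens as the wedge corrects and lengthens as the posterior
#' vertebrae grow.
#'
#' @param state A [spine_state()].
#' @param config A [sim_config()].
#' @return List `state` (advanced) and `record` (one-row data.frame of
#'   day, cobb_deg, tether_force_N, theta_deg, gm_percent, p_np_kpa).
#' @export
step_spine <- function(state, config) {
  seg <- config$segment
  dt <- config$dt
  x_rot <- axis_position(seg, config$axis)
  x_c <- seg$width + (if (config$tethered) config$construct$moment_arm_d else 10)
  scheme <- scheme_quarters()
  u <- config$baseline_profile$positions / seg$width
  idx <- region_index(u, scheme)
  ant <- idx == 1L; post <- idx == max(idx)
  gm_inst <- NA_real_; p_np <- NA_real_; defl_mean <- 0

  for (l in seq_len(config$n_levels)) {
    # (1) elastic equilibrium for current force
    theta_eq <- if (config$tethered && state$force[l] > 0) {
      equilibrium_angle(seg, config$construct, state$force[l], config$axis)$theta_eq_deg
    } else 0
    w_old <- state$disc_wedge[l]
    # (2) creep toward equilibrium shape
    target <- state$rest_wedge[l] - theta_eq
    state$disc_wedge[l] <- w_old + (target - w_old) * (1 - exp(-dt / config$creep_tau))
    # (3) disc stress relaxation: rest shape follows the held shape
    state$rest_wedge[l] <- state$rest_wedge[l] +
      (state$disc_wedge[l] - state$rest_wedge[l]) * (1 - exp(-dt / config$relax_tau))
    # (4) stress at the current elastic deflection
    defl <- state$rest_wedge[l] - state$disc_wedge[l]
    mech <- realign(seg, defl, x_rot)
    g <- modulated_rates(config$baseline_profile$growth_rate, config$params,
                         mech$sigma_gp)
    # (5) growth of the two facing physes
    dh_ant <- 2 * mean(g[ant]) * dt / 1000
    dh_post <- 2 * mean(g[post]) * dt / 1000
    state$vert_wedge[l] <- state$vert_wedge[l] +
      rad2deg(atan((dh_post - dh_ant) / seg$width))
    state$cum_height_mm[l] <- state$cum_height_mm[l] + 2 * mean(g) * dt / 1000
    # (6) cable force from construct stretch
    if (config$tethered) {
      dpath_corr <- (x_c - x_rot) *
        (tan(deg2rad(state$disc_wedge[l])) - tan(deg2rad(w_old)))
      dpath_growth <- 2 * g[length(g)] * dt / 1000
      state$force[l] <- max(0, state$force[l] +
                              config$construct$cable_stiffness *
                              (dpath_corr + dpath_growth))
    }
    if (l == 1L) {
      gm_inst <- 100 * (mean(g[ant]) - mean(g[post])) / mean(g)
      p_np <- mech$p_np
      defl_mean <- defl
    }
  }
  state$day <- state$day + dt
  rec <- data.frame(day = state$day, cobb_deg = cobb_angle(state),
                    tether_force_N = mean(state$force),
                    theta_deg = defl_mean, gm_percent = gm_inst,
                    p_np_kpa = mpa2kpa(p_np))
  list(state = state, record = rec)
}

#' Run a longitudinal tethering simulation
#'
#' Explicit-Euler time stepping of [step_spine()] from day 0 to the
#' configured duration.
#'
#' @param config A [sim_config()].
#' @return Object of class `vg_trajectory`: list with `config`, `final_state`
#'   and `trajectory` (data.frame of day, cobb_deg, tether_force_N,
#'   theta_deg, gm_percent, p_np_kpa).
#' @export
simulate_tethering <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  state <- spine_state(config)
  n_steps <- floor(config$duration / config$dt + 1e-9)
  recs <- vector("list", n_steps + 1)
  recs[[1]] <- data.frame(day = 0, cobb_deg = cobb_angle(state),
                          tether_force_N = mean(state$force),
                          theta_deg = 0, gm_percent = NA_real_,
                          p_np_kpa = mpa2kpa(config$segment$p0))
  for (k in seq_len(n_steps)) {
    stepped <- step_spine(state, config)
    state <- stepped$state
    recs[[k + 1]] <- stepped$record
  }
  structure(list(config = config, final_state = state,
                 trajectory = do.call(rbind, recs)), class = "vg_trajectory")
}

#' @export
print.vg_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<vg_trajectory> %s: Cobb %.1f -> %.1f deg over %d days\n",
              x$config$scenario, tr$cobb_deg[1], tr$cobb_deg[nrow(tr)],
              max(tr$day)))
  invisible(x)
}

#' Cobb-angle trajectories for the three study scenarios
#'
#' Runs the untreated, low-tension (5 N) and high-tension (25.6 N) scenarios
#' and returns their trajectories in one table.
#'
#' @param configs Named list of [sim_config()] objects; defaults to the three
#'   scenario presets.
#' @return data.frame with columns `scenario`, `day`, `cobb_deg`,
#'   `tether_force_N`, `theta_deg`, `gm_percent`, `p_np_kpa`.
#' @export
run_cohort_trajectories <- function(configs = list(
                                      untreated = sim_config("untreated"),
                                      low_tension = sim_config("low_tension"),
                                      high_tension = sim_config("high_tension"))) {
  rows <- lapply(names(configs), function(nm) {
    tr <- simulate_tethering(configs[[nm]])$trajectory
    cbind(scenario = nm, tr)
  })
  do.call(rbind, rows)
}
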