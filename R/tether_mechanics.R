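# Reduced-order sagittal mechanics of one vertebra-disc-vertebra unit under
# tether-driven realignment.
#
# The antero-posterior width is discretized into stations. A correction of
# theta about an axis at x_rot tilts the upper endplate, giving an affine
# disc-height change dh(x) = -(x - x_rot) * tan(theta): theta > 0 closes the
# posterior (convex) side. The nucleus pulposus responds as an incompressible
# pressurized compartment: its pressure rises as its volume is squeezed,
# p = max(0, p0 - (dV/V0)/C). Growth-plate axial stress (tension positive) is
# E_af * dh/h0 - p0 under the annulus and -p_np under the nucleus, so the
# uncorrected segment sits at the homeostatic stress -p0 everywhere.

#' Motion segment geometry and calibrated material parameters
#'
#' Defaults are the shipped calibration: with them the model reproduces a
#' baseline nucleus pressure of 0.15 MPa, a 0.005 MPa pressure drop for a 10
#' degree flexible-axis (disc-center) correction, and a 0.297 MPa rise for a
#' 10 degree stiff-axis (anterior-edge) correction. [calibrate_defaults()]
#' re-derives them from those three pressure targets.
#'
#' @param disc_height_h0 Disc height, mm.
#' @param radius_r Disc radius, mm (AP width = 2 * radius).
#' @param n_stations Number of AP stations.
#' @param E_af Effective axial modulus of the annulus-backed growth plate
#'   column, MPa.
#' @param np_compliance_C Nucleus pressure compliance, MPa^-1: fractional
#'   volume change per MPa of pressure change.
#' @param np_centroid_offset_delta AP offset of the nucleus footprint centroid
#'   from the disc center, mm (negative = anterior). A perfectly centered
#'   nucleus would see zero volume change under a disc-center rotation; the
#'   small calibrated anterior offset is what produces the small pressure
#'   drop seen with flexible-axis correction.
#' @param swelling_pressure_p0 Baseline (swelling) nucleus pressure, MPa.
#' @param initial_wedge_deg Initial kyphotic disc wedge, degrees (positive =
#'   kyphotic).
#' @param af_np_boundaries Fractions of the AP width where the anterior
#'   annulus / nucleus / posterior annulus regions meet.
#' @return Object of class `motion_segment`.
#' @export
motion_segment <- function(disc_height_h0 = 7, radius_r = 15, n_stations = 40,
                           E_af = 0.661649545622,
                           np_compliance_C = 1.25113751685,
                           np_centroid_offset_delta = -0.248344370861,
                           swelling_pressure_p0 = 0.15,
                           initial_wedge_deg = 10,
                           af_np_boundaries = c(0.25, 0.75)) {
  stopifnot(disc_height_h0 > 0, radius_r > 0, n_stations >= 4,
            E_af > 0, np_compliance_C > 0, swelling_pressure_p0 >= 0,
            length(af_np_boundaries) == 2, af_np_boundaries[1] > 0,
            af_np_boundaries[2] < 1, af_np_boundaries[1] < af_np_boundaries[2])
  structure(list(
    h0 = disc_height_h0, r = radius_r, width = 2 * radius_r,
    n_stations = as.integer(n_stations),
    E_af = E_af, C = np_compliance_C, delta = np_centroid_offset_delta,
    p0 = swelling_pressure_p0, initial_wedge_deg = initial_wedge_deg,
    af_np = af_np_boundaries
  ), class = "motion_segment")
}

#' @export
print.motion_segment <- function(x, ...) {
  cat(sprintf(paste0("<motion_segment> h0 %.1f mm, width %.0f mm, %d stations; ",
                     "E_af %.3f MPa, C %.3f MPa^-1, delta %+.3f mm, p0 %.3f MPa\n"),
              x$h0, x$width, x$n_stations, x$E_af, x$C, x$delta, x$p0))
  invisible(x)
}

#' Axis-of-rotation position for the named flexibility regime
#'
#' "flexible" rotates about the disc center (anterior distraction, posterior
#' compression, mid-disc height preserved); "stiff" rotates about the
#' anterior edge (anterior height preserved, everything else compressed).
#'
#' @param segment A [motion_segment()].
#' @param axis "flexible", "stiff", or a numeric x position in \[0, 2r\] mm.
#' @return Axis x-position in mm (0 = anterior edge).
#' @export
axis_position <- function(segment, axis) {
  if (is.numeric(axis)) {
    if (axis < 0 || axis > segment$width) stop("axis position outside the disc footprint")
    return(axis)
  }
  switch(match.arg(axis, c("flexible", "stiff")),
         flexible = segment$r, stiff = 0)
}

segment_stations <- function(segment) station_grid(segment$n_stations, segment$width)

# Fractional NP volume change for a given height field, by trapezoidal
# quadrature of dh over the (delta-shifted) nucleus footprint.
np_volume_change_frac <- function(segment, theta_rad, x_rot, n_quad = 201) {
  a <- segment$af_np[1] * segment$width + segment$delta
  b <- segment$af_np[2] * segment$width + segment$delta
  xq <- seq(a, b, length.out = n_quad)
  dhq <- -(xq - x_rot) * tan(theta_rad)
  h <- (b - a) / (n_quad - 1)
  dV <- h * (sum(dhq) - (dhq[1] + dhq[n_quad]) / 2)
  dV / ((b - a) * segment$h0)
}

#' Realign the motion segment by a rotation about a chosen axis
#'
#' Applies a correction of `theta_deg` about the axis at `x_rot` and returns
#' the resulting disc-height change field, growth-plate stress profile,
#' nucleus pressure, and the internal moment the disc exerts against the
#' correction. Positive theta closes the posterior side (corrects kyphosis).
#'
#' @param segment A [motion_segment()].
#' @param theta_deg Correction angle, degrees.
#' @param axis "flexible", "stiff", or a numeric axis position in mm.
#' @param construct Optional [tether_construct()]; when given, the cable
#'   force required to hold this state is reported as `tether_force_F`.
#' @return Object of class `realignment_state`: `theta_deg`, `x_rot`,
#'   `stations`, `dh` (mm), `strain`, `sigma_gp` (MPa, tension positive),
#'   `p_np` (MPa), `delta_p` (MPa), `required_moment` (N mm),
#'   `tether_force_F` (N per cable, NA without a construct).
#' @export
realign <- function(segment, theta_deg, axis = "flexible", construct = NULL) {
  stopifnot(inherits(segment, "motion_segment"))
  x_rot <- axis_position(segment, axis)
  theta <- deg2rad(theta_deg)
  x <- segment_stations(segment)
  dh <- -(x - x_rot) * tan(theta)
  closed <- which(segment$h0 + dh <= 0)
  if (length(closed) > 0) {
    stop(sprintf("disc height closes at station %d (x = %.2f mm): |theta| too large",
                 closed[1], x[closed[1]]))
  }
  vfrac <- np_volume_change_frac(segment, theta, x_rot)
  p_np <- max(0, segment$p0 - vfrac / segment$C)
  u <- x / segment$width
  af <- u < segment$af_np[1] | u >= segment$af_np[2]
  sigma <- numeric(length(x))
  sigma[af] <- segment$E_af * dh[af] / segment$h0 - segment$p0
  sigma[!af] <- -p_np
  # internal restoring moment about the axis, per unit construct (depth = width)
  dsig <- sigma - (-segment$p0)
  dx <- segment$width / segment$n_stations
  m_int <- -segment$width * sum(dsig * (x - x_rot)) * dx
  out <- structure(list(
    theta_deg = theta_deg, x_rot = x_rot, stations = x,
    dh = dh, strain = dh / segment$h0, sigma_gp = sigma,
    p_np = p_np, delta_p = p_np - segment$p0,
    required_moment = m_int, tether_force_F = NA_real_,
    segment = segment
  ), class = "realignment_state")
  if (!is.null(construct)) {
    arm <- (segment$width + construct$moment_arm_d) - x_rot
    out$tether_force_F <- m_int / (construct$n_cables * arm)
  }
  out
}

#' @export
print.realignment_state <- function(x, ...) {
  cat(sprintf(paste0("<realignment_state> theta %.2f deg about x = %.1f mm; ",
                     "p_np %.3f MPa (delta %+.3f); sigma range [%.3f, %.3f] MPa\n"),
              x$theta_deg, x$x_rot, x$p_np, x$delta_p,
              min(x$sigma_gp), max(x$sigma_gp)))
  invisible(x)
}

#' Disc-height change at an arbitrary AP position
#'
#' The height-change field is affine, `dh(x) = -(x - x_rot) * tan(theta)`;
#' this evaluates it anywhere (e.g. exactly at mid-disc or at an edge),
#' independent of the station grid.
#'
#' @param state A [realign()] result.
#' @param x AP position(s), mm.
#' @return Height change(s), mm.
#' @export
dh_at <- function(state, x) {
  stopifnot(inherits(state, "realignment_state"))
  -(x - state$x_rot) * tan(deg2rad(state$theta_deg))
}

#' Tether construct parameters
#'
#' @param pretension Cable pretension at implantation, N (study arms: 5 N low,
#'   25.6 N high).
#' @param n_cables Number of cables (bilateral pair by default).
#' @param moment_arm_d Posterior offset of the cable line from the posterior
#'   disc edge, mm (screw-head position surrogate).
#' @param cable_stiffness Cable axial stiffness, N/mm, used by the
#'   longitudinal simulator's force update.
#' @param levels Number of instrumented disc spaces.
#' @return Object of class `tether_construct`.
#' @export
tether_construct <- function(pretension = 5, n_cables = 2, moment_arm_d = 10,
                             cable_stiffness = 5, levels = 1L) {
  stopifnot(pretension >= 0, n_cables >= 1, moment_arm_d > 0, cable_stiffness >= 0)
  structure(list(pretension = pretension, n_cables = as.integer(n_cables),
                 moment_arm_d = moment_arm_d, cable_stiffness = cable_stiffness,
                 levels = as.integer(levels)), class = "tether_construct")
}

# Largest admissible positive correction before posterior contact.
theta_limit <- function(segment, x_rot) {
  x <- segment_stations(segment)
  span <- max(x) - x_rot
  if (span <= 0) return(pi / 2)
  atan(segment$h0 / span)
}

#' Cable force required to hold a prescribed correction
#'
#' Inverse of [equilibrium_angle()]: the per-cable force whose moment about
#' the axis balances the disc's internal restoring moment at `theta_deg`.
#'
#' @inheritParams realign
#' @param construct A [tether_construct()].
#' @return Force per cable, N.
#' @export
required_force <- function(segment, construct, theta_deg, axis = "flexible") {
  x_rot <- axis_position(segment, axis)
  st <- realign(segment, theta_deg, x_rot)
  arm <- (segment$width + construct$moment_arm_d) - x_rot
  st$required_moment / (construct$n_cables * arm)
}

#' Equilibrium correction angle under a given cable force
#'
#' Solves the rotational equilibrium F_total * arm = M_disc(theta), where
#' M_disc integrates the station stress changes times their lever arms about
#' the axis. Larger force gives larger correction; sufficiently large force
#' corrects past neutral into lordosis.
#'
#' @inheritParams required_force
#' @param force Force per cable, N (>= 0).
#' @return List with `theta_eq_deg`, `state` (the [realign()] result at
#'   equilibrium) and `residual` (N mm).
#' @export
equilibrium_angle <- function(segment, construct, force, axis = "flexible") {
  stopifnot(force >= 0)
  x_rot <- axis_position(segment, axis)
  arm <- (segment$width + construct$moment_arm_d) - x_rot
  target <- construct$n_cables * force * arm
  f <- function(th) target - realign(segment, th, x_rot)$required_moment
  if (force == 0) {
    st <- realign(segment, 0, x_rot)
    return(list(theta_eq_deg = 0, state = st, residual = 0))
  }
  hi <- rad2deg(theta_limit(segment, x_rot)) * 0.999
  if (f(hi) > 0) {
    stop(sprintf(paste0("no equilibrium below posterior contact: moment demand ",
                        "%.1f N mm exceeds disc capacity %.1f N mm on theta in ",
                        "[0, %.2f] deg"), target, target - f(hi), hi))
  }
  sol <- uniroot(f, c(0, hi), tol = 1e-12)
  th <- sol$root
  # secant polish for a tight moment residual
  for (i in 1:3) {
    r0 <- f(th)
    if (abs(r0) < 1e-10) break
    dth <- 1e-7
    slope <- (f(th + dth) - r0) / dth
    th <- th - r0 / slope
  }
  st <- realign(segment, th, x_rot, construct = construct)
  list(theta_eq_deg = th, state = st, residual = f(th))
}

#' Equilibrium angle and nucleus pressure along a tether load schedule
#'
#' @inheritParams required_force
#' @param force_grid Non-decreasing vector of per-cable forces, N.
#' @return data.frame with columns `force_N`, `theta_eq_deg`,
#'   `apical_angle_deg` (initial wedge minus correction; negative =
#'   lordotic), `p_np_kPa`.
#' @export
pressure_load_curve <- function(segment, construct, force_grid, axis = "flexible") {
  stopifnot(all(force_grid >= 0), !is.unsorted(force_grid))
  rows <- lapply(force_grid, function(F) {
    eq <- equilibrium_angle(segment, construct, F, axis)
    data.frame(force_N = F, theta_eq_deg = eq$theta_eq_deg,
               apical_angle_deg = segment$initial_wedge_deg - eq$theta_eq_deg,
               p_np_kPa = mpa2kpa(eq$state$p_np))
  })
  do.call(rbind, rows)
}

#' Calibrate the surrogate to the three reference nucleus pressures
#'
#' Sets the swelling pressure to the baseline target directly, then solves a
#' 2x2 system numerically for the nucleus compliance and centroid offset so
#' that a 10 degree flexible-axis (disc-center) correction changes the
#' pressure by the flexible target and a 10 degree stiff-axis (anterior-edge)
#' correction by the stiff target, each within 1e-4 MPa. The annulus modulus
#' is set by the documented rule that the stiff correction drives the
#' posterior disc edge exactly to the growth-arrest threshold beyond the
#' swelling prestress: E_af = sigma_arrest * h0 / (2r * tan(10 deg)).
#'
#' @param targets Named numeric: `baseline` pressure (MPa), `flexible` and
#'   `stiff` pressure changes (MPa) for the 10 degree corrections.
#' @param theta_deg Correction angle of the two calibration scenarios.
#' @param disc_height_h0,radius_r,n_stations Geometry (see
#'   [motion_segment()]).
#' @param sigma_arrest Growth-arrest threshold used by the E_af rule, MPa.
#' @return List with the calibrated `swelling_pressure_p0`,
#'   `np_compliance_C`, `np_centroid_offset_delta`, `E_af`, the `achieved`
#'   pressure changes, and the `segment` built from them.
#' @export
calibrate_defaults <- function(targets = c(baseline = 0.15, flexible = -0.005,
                                           stiff = 0.297),
                               theta_deg = 10, disc_height_h0 = 7, radius_r = 15,
                               n_stations = 40, sigma_arrest = 0.5) {
  stopifnot(all(is.finite(targets)),
            all(c("baseline", "flexible", "stiff") %in% names(targets)))
  if (targets[["flexible"]] >= 0 || targets[["stiff"]] <= 0) {
    stop("expected a pressure decrease for the flexible axis and an increase for the stiff axis")
  }
  p0 <- targets[["baseline"]]
  theta <- deg2rad(theta_deg)
  E_af <- sigma_arrest * disc_height_h0 / (2 * radius_r * tan(theta))
  seg_for <- function(delta, C) {
    motion_segment(disc_height_h0, radius_r, n_stations, E_af, C, delta, p0)
  }
  # For a given centroid offset, the compliance follows from the flexible
  # target; the stiff target then determines the offset by root finding.
  C_of <- function(delta) {
    vf <- np_volume_change_frac(seg_for(delta, 1), theta, radius_r)
    -vf / targets[["flexible"]]
  }
  resid <- function(delta) {
    C <- C_of(delta)
    if (C <= 0) return(NA_real_)
    st <- realign(seg_for(delta, C), theta_deg, 0)
    st$delta_p - targets[["stiff"]]
  }
  lo <- -radius_r / 2; hi <- -1e-6
  rl <- resid(lo); rh <- resid(hi)
  if (!is.finite(rl) || !is.finite(rh) || rl * rh > 0) {
    stop(sprintf(paste0("no calibration root in offset bracket [%.3f, %.3f] mm ",
                        "(residuals %.4g / %.4g MPa)"), lo, hi, rl, rh))
  }
  delta <- uniroot(resid, c(lo, hi), tol = 1e-12)$root
  C <- C_of(delta)
  seg <- seg_for(delta, C)
  achieved <- c(baseline = realign(seg, 0, radius_r)$p_np,
                flexible = realign(seg, theta_deg, radius_r)$delta_p,
                stiff = realign(seg, theta_deg, 0)$delta_p)
  err <- abs(achieved - targets[c("baseline", "flexible", "stiff")])
  if (any(err > 1e-4)) {
    stop(sprintf("calibration residual %.2g MPa exceeds 1e-4 MPa", max(err)))
  }
  list(swelling_pressure_p0 = p0, np_compliance_C = C,
       np_centroid_offset_delta = delta, E_af = E_af,
       achieved = achieved, segment = seg)
}
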