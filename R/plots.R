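# Optional ggplot2 figures (ggplot2 is suggested, not imported).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the CSV outputs")
  }
}

#' Plot growth-plate stress and predicted growth across the AP width
#'
#' @param state A [realign()] result.
#' @param params Optional [growth_law_params()]; when given, the predicted
#'   growth field is drawn on a second panel scale.
#' @return A ggplot object.
#' @export
plot_stress_profile <- function(state, params = NULL) {
  need_ggplot()
  df <- data.frame(x = state$stations, sigma = state$sigma_gp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$sigma)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -0.5, linetype = "dashed") +
    ggplot2::labs(x = "position from anterior edge (mm)",
                  y = "growth-plate stress (MPa, tension +)",
                  title = sprintf("theta = %.1f deg, axis at %.1f mm",
                                  state$theta_deg, state$x_rot))
  p
}

#' Plot Cobb-angle and tether-force trajectories by scenario
#'
#' @param trajectories Output of [run_cohort_trajectories()].
#' @param what "cobb" or "force".
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, what = c("cobb", "force")) {
  need_ggplot()
  what <- match.arg(what)
  yvar <- if (what == "cobb") "cobb_deg" else "tether_force_N"
  ylab <- if (what == "cobb") "instrumented Cobb angle (deg)" else "tether force (N)"
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$day, y = .data[[yvar]],
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days post-op", y = ylab)
}
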