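# Regional physeal growth rates and the percent growth modulation statistic.
#
# The anatomical rationale for the default quarter-half-quarter division: the
# annulus fibrosus attaches over roughly the outer quarters of the vertebral
# width while the nucleus pulposus occupies the central half, so tether forces
# are transmitted differently to the peripheral and central growth plate.

#' Region scheme partitioning the antero-posterior width
#'
#' @param boundaries Strictly increasing fractions in (0, 1) splitting the
#'   normalized AP coordinate into regions. Region intervals are half-open
#'   `[lo, hi)`; the last region is closed.
#' @param labels One name per region; the first must be the anterior region
#'   and the last the posterior region.
#' @return Object of class `region_scheme`.
#' @export
region_scheme <- function(boundaries, labels) {
  stopifnot(is.numeric(boundaries), length(labels) == length(boundaries) + 1L)
  if (any(boundaries <= 0) || any(boundaries >= 1) || any(diff(boundaries) <= 0)) {
    stop("region boundaries must be strictly increasing fractions in (0, 1)")
  }
  structure(list(boundaries = as.numeric(boundaries), labels = as.character(labels)),
            class = "region_scheme")
}

#' @rdname region_scheme
#' @export
scheme_quarters <- function() {
  region_scheme(c(0.25, 0.75), c("anterior", "middle", "posterior"))
}

#' @rdname region_scheme
#' @export
scheme_halves <- function() region_scheme(0.5, c("anterior", "posterior"))

#' @rdname region_scheme
#' @export
scheme_thirds <- function() {
  region_scheme(c(1, 2) / 3, c("anterior", "middle", "posterior"))
}

#' @rdname region_scheme
#' @export
scheme_fourths <- function() {
  region_scheme(c(0.25, 0.5, 0.75),
                c("anterior", "mid_anterior", "mid_posterior", "posterior"))
}

# Station -> region index. Half-open [lo, hi), last region closed at 1.
region_index <- function(u, scheme) {
  edges <- c(0, scheme$boundaries, 1)
  idx <- findInterval(u, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(scheme$labels))
}

#' Growth rate from fluorochrome label distance
#'
#' Distance between the two fluorochrome mineralization fronts divided by the
#' labeling interval, expressed in um/day.
#'
#' @param label_distance_mm Distance(s) in mm, non-negative.
#' @param interval_days Days between labels (> 0).
#' @return Growth rate(s) in um/day.
#' @examples
#' growth_rate_from_labels(2.4, 13) # 184.6 um/day
#' @export
growth_rate_from_labels <- function(label_distance_mm, interval_days) {
  if (!is.numeric(interval_days) || length(interval_days) != 1L || interval_days <= 0) {
    stop("labeling interval must be a positive number of days")
  }
  if (any(label_distance_mm < 0)) stop("label distances must be non-negative")
  um_per_day(label_distance_mm, interval_days)
}

#' Regional growth rates of a physis profile
#'
#' Station means within each region of `scheme`. The whole-physis mean is the
#' mean over all stations (not the mean of region means, whose widths differ).
#'
#' @param profile A [physis_profile()].
#' @param scheme A [region_scheme()] (default quarter-half-quarter).
#' @param unossified_fraction Optional anterior fraction reported additionally
#'   as the anterior unossified epiphysis rate (its extent varies from sample
#'   to sample, so it is a tunable tag, not a fixed region).
#' @return Object of class `regional_growth_rates`: `per_region_mean` (named),
#'   `whole_physis_mean`, `n_stations` per region, `scheme`, and optionally
#'   `anterior_unossified_mean`.
#' @export
regionalize <- function(profile, scheme = scheme_quarters(),
                        unossified_fraction = NULL) {
  stopifnot(inherits(profile, "physis_profile"), inherits(scheme, "region_scheme"))
  u <- profile$positions / profile$ap_width_mm
  idx <- region_index(u, scheme)
  counts <- tabulate(idx, nbins = length(scheme$labels))
  if (any(counts == 0)) {
    stop(sprintf("region '%s' contains no stations",
                 scheme$labels[which(counts == 0)[1]]))
  }
  means <- vapply(seq_along(scheme$labels),
                  function(k) mean(profile$growth_rate[idx == k]), numeric(1))
  out <- structure(list(
    per_region_mean = setNames(means, scheme$labels),
    whole_physis_mean = mean(profile$growth_rate),
    n_stations = setNames(counts, scheme$labels),
    scheme = scheme
  ), class = "regional_growth_rates")
  if (!is.null(unossified_fraction)) {
    stopifnot(unossified_fraction > 0, unossified_fraction < 1)
    sel <- u < unossified_fraction
    if (!any(sel)) stop("anterior unossified fraction contains no stations")
    out$anterior_unossified_mean <- mean(profile$growth_rate[sel])
  }
  out
}

#' @export
print.regional_growth_rates <- function(x, ...) {
  cat("<regional_growth_rates>\n")
  print(round(x$per_region_mean, 2))
  cat(sprintf("whole physis: %.2f um/day\n", x$whole_physis_mean))
  invisible(x)
}

#' Percent growth modulation
#'
#' 100 * (anterior rate - posterior rate) / whole-physis mean rate. Positive
#' values (anterior growing faster than posterior) are corrective in
#' kyphosis; negative values indicate worsening kyphosis. Normalizing by the
#' animal's own mean rate removes between-animal differences in overall
#' growth velocity.
#'
#' @param anterior,posterior Anterior- and posterior-region mean rates, um/day.
#' @param total_mean Whole-physis mean rate, um/day (> 0).
#' @return Object of class `growth_modulation_result` with `gm_percent`,
#'   `anterior_rate`, `posterior_rate`, `total_mean_rate`.
#' @export
growth_modulation <- function(anterior, posterior, total_mean) {
  stopifnot(is.numeric(anterior), is.numeric(posterior), is.numeric(total_mean))
  if (total_mean <= 0) stop("whole-physis mean rate must be positive")
  structure(list(
    gm_percent = 100 * (anterior - posterior) / total_mean,
    anterior_rate = anterior, posterior_rate = posterior,
    total_mean_rate = total_mean
  ), class = "growth_modulation_result")
}

#' @export
print.growth_modulation_result <- function(x, ...) {
  cat(sprintf("<growth_modulation> %.1f%% (ant %.1f, post %.1f, mean %.1f um/day)\n",
              x$gm_percent, x$anterior_rate, x$posterior_rate, x$total_mean_rate))
  invisible(x)
}

#' Percent growth modulation of a profile under a scheme
#'
#' Regionalizes and applies [growth_modulation()] using the scheme's outermost
#' regions as anterior and posterior.
#'
#' @inheritParams regionalize
#' @return A `growth_modulation_result`.
#' @export
growth_modulation_profile <- function(profile, scheme = scheme_quarters()) {
  reg <- if (inherits(profile, "regional_growth_rates")) profile
         else regionalize(profile, scheme)
  m <- reg$per_region_mean
  growth_modulation(m[[1]], m[[length(m)]], reg$whole_physis_mean)
}

#' Tethered-space rates: sum of the two physes facing one tethered disc
#'
#' Elementwise sum of the distal physis of the proximal vertebra and the
#' proximal physis of the distal vertebra, region by region. Both inputs must
#' use the same region scheme.
#'
#' @param proximal_distal,distal_proximal `regional_growth_rates` for the two
#'   facing physes.
#' @return Object of class `tethered_space_rates` (inherits
#'   `regional_growth_rates`).
#' @export
tethered_space <- function(proximal_distal, distal_proximal) {
  stopifnot(inherits(proximal_distal, "regional_growth_rates"),
            inherits(distal_proximal, "regional_growth_rates"))
  a <- proximal_distal$scheme; b <- distal_proximal$scheme
  if (!identical(a$labels, b$labels) || !isTRUE(all.equal(a$boundaries, b$boundaries))) {
    stop("the two physes use different region schemes")
  }
  structure(list(
    per_region_mean = proximal_distal$per_region_mean + distal_proximal$per_region_mean,
    whole_physis_mean = proximal_distal$whole_physis_mean + distal_proximal$whole_physis_mean,
    n_stations = proximal_distal$n_stations,
    scheme = a
  ), class = c("tethered_space_rates", "regional_growth_rates"))
}

#' Sensitivity of percent growth modulation to the regional division
#'
#' Recomputes the statistic under alternative divisions of the AP width
#' (halves, thirds, quarters, ...), using each scheme's outermost regions as
#' anterior/posterior. Coarser outer regions mix the unmodulated central zone
#' into the peripheral averages and dilute the detectable modulation.
#'
#' @param profile A [physis_profile()].
#' @param schemes Named list of [region_scheme()] objects. Defaults to the
#'   quarter-half-quarter reference plus halves, thirds and fourths.
#' @return data.frame with columns `scheme`, `anterior_rate`,
#'   `posterior_rate`, `total_mean_rate`, `gm_percent`.
#' @export
region_scheme_sensitivity <- function(profile,
                                      schemes = list(quarters = scheme_quarters(),
                                                     halves = scheme_halves(),
                                                     thirds = scheme_thirds(),
                                                     fourths = scheme_fourths())) {
  stopifnot(length(schemes) >= 1)
  if (is.null(names(schemes))) names(schemes) <- paste0("scheme", seq_along(schemes))
  rows <- lapply(names(schemes), function(nm) {
    gm <- growth_modulation_profile(profile, schemes[[nm]])
    data.frame(scheme = nm, anterior_rate = gm$anterior_rate,
               posterior_rate = gm$posterior_rate,
               total_mean_rate = gm$total_mean_rate,
               gm_percent = gm$gm_percent)
  })
  do.call(rbind, rows)
}

#' Two-group comparison by Student t-test
#'
#' Classic equal-variance two-tailed Student t-test for unpaired groups,
#' paired t-test for within-animal comparisons, significance flagged at
#' p <= 0.05. Degenerate zero-variance cases (which `t.test` refuses) are
#' handled explicitly: identical constant groups give t = 0, p = 1; a paired
#' design with constant non-zero difference gives p = 0.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each; equal length if
#'   paired).
#' @param paired Within-animal comparison?
#' @return List with `t`, `df`, `p`, `means`, `sds`, `significant`.
#' @export
cohort_compare <- function(group_a, group_b, paired = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("at least two observations per group are required")
  }
  if (paired && length(group_a) != length(group_b)) {
    stop("paired comparison requires equal group sizes")
  }
  out <- list(means = c(a = mean(group_a), b = mean(group_b)),
              sds = c(a = sd(group_a), b = sd(group_b)))
  if (paired) {
    d <- group_a - group_b
    if (sd(d) == 0) {
      out$t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      out$df <- length(d) - 1
      out$p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(group_a, group_b, paired = TRUE)
      out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
      out$p <- tt$p.value
    }
  } else {
    if (sd(group_a) == 0 && sd(group_b) == 0) {
      eq <- mean(group_a) == mean(group_b)
      out$t <- if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf
      out$df <- length(group_a) + length(group_b) - 2
      out$p <- if (eq) 1 else 0
    } else {
      tt <- t.test(group_a, group_b, var.equal = TRUE)
      out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
      out$p <- tt$p.value
    }
  }
  out$significant <- out$p <= 0.05
  out
}
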