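# Shared fixtures: all built in code at test time.

# Muffle the generator's clamping warnings where clamping is expected.
quiet_gen <- function(expr) {
  withCallingHandlers(expr, vertegrow_clamp_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

flat_profile <- function(rate = 178, n = 40, width = 30) {
  gen_growth_profile(rate, 0, n_stations = n, ap_width_mm = width)
}

# A peripherally modulated reference profile.
modulated_profile <- function(rate = 178, gm = 53, loc = 0.25, n = 40) {
  gen_growth_profile(rate, gm, localization = loc, n_stations = n)
}

noiseless_spec <- function(gm = 53, rate = 178, n_animals = 2, seed = 7) {
  cohort_spec("fixture", n_animals, rate, 0, gm, 0,
              measurement_noise_sd = 0, seed = seed)
}
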