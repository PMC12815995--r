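# vertegrow

Analysis and simulation of **tether-mediated vertebral growth modulation**
in the growing kyphotic spine, for researchers studying posterior vertebral
body tethering (pVBT) and, more generally, mechanically guided growth at
vertebral physes.

Growth plates respond to load (the Hueter-Volkmann principle: compression
slows growth, tension accelerates it), and a posterior tether exploits this
to correct a kyphotic deformity with the patient's own remaining growth.
`vertegrow` implements the full quantitative chain:

* **Growth metrics.** Regional physeal growth rates from pulsed
  fluorochrome label distances (rate = 1000 · distance / interval), the
  quarter-half-quarter regional division of the antero-posterior width, and
  the percent growth modulation statistic

  ```
  %GM = 100 × (anterior-¼ rate − posterior-¼ rate) / whole-physis mean rate
  ```

  with alternative region schemes (halves/thirds/fourths), tethered-space
  aggregation, and Student t-test cohort comparisons.
* **Tether mechanics.** A calibrated reduced-order sagittal motion segment
  (disc height 7 mm, width 30 mm): affine disc-height field
  `dh(x) = −(x − x_rot)·tanθ` under a correction θ about a configurable
  axis of rotation, an incompressible nucleus-pulposus pressure compliance
  law, growth-plate stress profiles, and force-angle equilibrium under a
  cable construct. The shipped calibration reproduces a 0.15 MPa baseline
  nucleus pressure, a −0.005 MPa change for a 10° *flexible* (disc-center
  axis) correction and a +0.297 MPa change for a 10° *stiff*
  (anterior-edge axis) correction.
* **Growth dynamics.** A linear stress-modulated growth law with growth
  arrest at 0.5 MPa compression, stress-to-%GM prediction, and a
  longitudinal Cobb-angle simulator with emergent biphasic (early
  load-dependent, late load-independent) correction.
* **Synthetic cohorts.** A generator with stored latent truth emulating the
  study's cohorts (e.g. apical growth rate 178 ± 21 µm/day, high-tension
  %GM 53 ± 43), so every pipeline stage is testable by parameter recovery.

See `vignettes/growth-modulation-methods.Rmd` for the models, assumptions,
parameter defaults and limitations.

## Worked example

Generate a high-tension single-level cohort, analyze it, and compare the
mechanics of flexible vs stiff correction:

```r
library(vertegrow)

spec <- cohort_presets()$single_high   # 4 animals, %GM ~ Normal(53, 43)
spec$seed <- 42
cohort <- gen_cohort(spec)
res <- analyze_growth(cohort)
res$cohort
#>        cohort n_animals mean_rate  sd_rate  gm_mean    gm_sd
#> 1 single_high         4  174.6376 27.56741 51.52299 37.10869
```

Four simulated animals recover a cohort %GM of 51.5 ± 37.1 — one draw from
the 53 ± 43 study condition; across many replicate cohorts the grand mean
converges on 53. An unpaired Student t-test against a control-like group
flags the high-tension effect:

```r
cc <- cohort_compare(res$per_animal$gm_percent, c(-12, 5, -20, 9))
#> t = 2.83, p = 0.030
```

The calibrated motion segment, corrected 10° about the two axes:

```r
seg <- motion_segment()
realign(seg, 10, "flexible")
#> <realignment_state> theta 10.00 deg about x = 15.0 mm; p_np 0.145 MPa
#>   (delta -0.005); sigma range [-0.394, 0.094] MPa
realign(seg, 10, "stiff")
#> <realignment_state> theta 10.00 deg about x = 0.0 mm; p_np 0.447 MPa
#>   (delta +0.297); sigma range [-0.644, -0.156] MPa
```

The flexible correction drops nucleus pressure slightly and spans anterior
tension (+0.09 MPa) to posterior compression (−0.39 MPa) — every station
inside the 0.5 MPa arrest threshold, so the growth law predicts strong
positive modulation. The stiff correction raises nucleus pressure by
0.297 MPa and pushes the posterior stations past the threshold, predicting
regional growth arrest instead of modulation:

```r
predict_modulation_from_stress(realign(seg, 10, "flexible"),
                               growth_law_params(g0 = 178))$modulation
#> <growth_modulation> 106.4% (ant 273.4, post 82.6, mean 179.3 um/day)
```

Longitudinal scenarios (untreated progression, 5 N and 25.6 N tethers):

```r
trajectories <- run_cohort_trajectories()
```

A shell entry point wraps the same drivers:
`exec/vertegrow generate|analyze|simulate-mechanics|simulate-growth|predict-modulation|replicate`,
each with `--config`, `--seed`, `--out`. `cmd_replicate()` runs the whole
chain (calibration, the three pressure scenarios, load curves, predicted
modulation profiles, cohort recoveries, trajectories) into one report
directory in about a minute.

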