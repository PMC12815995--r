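---
title: "Models and methods: tether-mediated vertebral growth modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tether-mediated vertebral growth modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertegrow)
```

# The problem

Posterior vertebral body tethering (pVBT) anchors a flexible cable to the
posterior elements of a kyphotic spine so that the remaining growth of the
instrumented vertebrae corrects the deformity: by the Hueter-Volkmann
principle, compression across a physis slows longitudinal growth and tension
accelerates it. `vertegrow` implements the quantitative chain this therapy
relies on:

1. measurement — regional physeal growth rates from pulsed fluorochrome
   label distances and the percent growth modulation (%GM) statistic;
2. mechanics — how a tether load redistributes disc height, nucleus
   pulposus (NP) pressure and growth-plate stress across the
   antero-posterior (AP) width, depending on where the axis of rotation
   sits;
3. growth dynamics — a stress-modulated growth law with an arrest
   threshold, integrated in time to produce Cobb-angle trajectories;
4. synthesis — a cohort generator with known latent truth, so every
   analysis stage is testable by parameter recovery.

# The growth modulation statistic

For one physis profiled at stations across the AP width,

$$\%\mathrm{GM} \;=\; 100 \times
\frac{\bar g_{\mathrm{ant\,1/4}} - \bar g_{\mathrm{post\,1/4}}}
     {\bar g_{\mathrm{whole}}},$$

where the anterior and posterior quarters are station means within the outer
quarters of the width and the denominator is the mean over *all* stations
(not the mean of region means — the quarter/half/quarter regions have
unequal widths). Positive %GM (anterior outgrowing posterior) is corrective
in kyphosis. Normalizing by the animal's own mean rate removes
between-animal growth-velocity differences, which is also why cohort %GM is
summarized as the mean of per-animal ratios rather than the ratio of cohort
means.

The quarter-half-quarter division is anatomical: the annulus fibrosus
attaches over roughly the outer quarters and the nucleus occupies the
central half, and the stress gradients a tether induces are concentrated
peripherally. `region_scheme_sensitivity()` quantifies the corollary:
halving or thirding the width mixes the unmodulated central zone into the
outer averages and dilutes the detectable signal, so
$|\%GM_{1/4}| \ge |\%GM_{1/3}| \ge |\%GM_{1/2}|$ for peripherally localized
modulation. Region intervals are half-open $[lo, hi)$ in normalized
position, with the last region closed, so station assignment at boundaries
is unambiguous; the default station grid places stations at bin midpoints so
no station ever sits on a boundary.

Rates derive from label distances as
$g = 1000\,d_{\mathrm{mm}} / \Delta t_{\mathrm{days}}\ \mu m/day$, with
the two labels nominally 12-14 days apart (13 by default). For tethered
levels the measured unit is the *tethered space*: the elementwise sum of the
two physes facing the tethered disc.

# The synthetic cohort generator

`gen_cohort()` emulates the study's measurement structure: per animal, a
base growth rate and a latent %GM are drawn from the cohort's Normal
distributions, a deterministic station profile realizing that %GM exactly is
built, and independent station-level Normal measurement noise is added to
each physis. Cohort presets carry the study conditions: apical rates
178 ± 21 µm/day (11-week controls) and 173 ± 28 (13-week), and %GM
distributions 53 ± 43 (high-tension single-level), −1 ± 15 (low-tension
single-level), 14 ± 11 / 10 ± 10 (multi-level low/high).

Design choices that were genuinely open:

* **Profile shape.** Modulation is carried by cubic smoothstep ramps
  confined to the outer `localization` fraction (default 0.25) of each end,
  with a flat central zone — the simplest shape consistent with
  peripherally concentrated stress gradients. The inversion is exact: given
  a base rate and a %GM target, the ramp amplitude follows in closed form
  from the station means of the shape, so noiseless profiles round-trip
  through the analysis with zero error.
* **Extreme draws.** A symmetric profile (equal anterior/posterior
  amplitudes) can only realize |%GM| up to about 100% with non-negative
  rates, but a 53 ± 43 distribution has substantial mass beyond that. The
  generator therefore falls back to asymmetric amplitudes — the posterior
  ramp lowered until it just touches zero, the remainder carried
  anteriorly — which realizes targets to about ±400% exactly and keeps
  cohort recovery asymptotically unbiased. Draws beyond even that range are
  clamped at zero with a classed warning, and the *realized* latent truth
  (recomputed from the clamped profile) is stored with the record, so
  recovery tests compare against what was actually generated. The
  user-facing deterministic constructor `gen_growth_profile()` keeps the
  symmetric shape and raises an error when the target is unrealizable.
* **Noise model.** The study reports only cohort-level mean ± SD; the
  additive station-level Normal noise (default SD 10 µm/day) is the simplest
  structure consistent with that, and its default is a package choice, not a
  reported value. The same is true of the %GM spread assigned to the
  non-kyphotic control presets and of the two-physes-per-level layout
  (both facing physes share the animal's latent parameters).

What the generator does *not* emulate: spatially correlated measurement
error, within-animal between-level heterogeneity, the variable extent of
the anterior unossified epiphysis, and any age-related decline in growth
rate. Passing recovery tests therefore demonstrate that the pipeline's
estimators are correct and unbiased under the stated noise model — not that
the animal study's biological variability is fully captured.

A note on units: printed apical rates are sums over the two physes of a
vertebra, but the generator parameterizes the *measured profile* directly
with the cohort mean, so per-physis, per-animal and tethered-space analyses
all recover the same latent %GM. Only ratios are affected by this
convention, never the %GM statistic itself.

# The reduced-order motion segment

The full finite-element simulation this surrogate stands in for is a 3-D
triphasic model; its material constants are not available, but its three
headline NP pressures are, and they fully determine a small 1-D model. The
AP width (2r = 30 mm, disc height 7 mm) is discretized into stations
(default 40; results change by well under 0.5% at 400). A correction of
$\theta$ about an axis at $x_{rot}$ changes disc height affinely:

$$dh(x) = -(x - x_{rot})\tan\theta,$$

with $\theta > 0$ closing the posterior side. The two named regimes encode
the defining kinematic contracts: a *flexible* disc rotates about its
center (mid-disc height exactly preserved, anterior distraction, posterior
compression) and a *stiff* disc about its anterior edge (anterior height
exactly preserved, everything else compressed). The second-order uniform
height change $h_0(\cos\theta - 1)$ (< 1.6% at 10°) is neglected; the
calibration absorbs it.

The nucleus is an incompressible pressurized compartment occupying the
central half of the width, its footprint shifted by a small calibrated
offset $\delta$. Its pressure follows a compliance law

$$p_{np} = \max\!\left(0,\; p_0 - \frac{\Delta V / V_0}{C}\right),$$

with $\Delta V$ the quadrature integral of $dh$ over the footprint: squeeze
the nucleus and its pressure rises. Growth-plate axial stress (tension
positive) is $E_{af}\,dh/h_0 - p_0$ under the annulus and $-p_{np}$ under
the nucleus, so the uncorrected segment sits at the homeostatic stress
$-p_0$ everywhere and the stress field is continuous in $\theta$ at zero.

**Calibration.** The three reference pressures are: baseline 0.15 MPa
(within the 0.1-0.21 MPa literature range), a 0.005 MPa *decrease* for a
10° flexible-axis correction, and a 0.297 MPa *increase* for a 10°
stiff-axis correction. The baseline fixes $p_0$ directly. Because $dh$ is
affine, a perfectly centered nucleus would see zero volume change under a
disc-center rotation; the small pressure decrease therefore requires a
slight footprint offset, and its *direction* is dictated by the signs: an
anterior offset (calibrated $\delta = -0.248$ mm) puts the footprint
centroid on the distraction side of the center axis (volume gain, pressure
drop) while the anterior-edge axis still compresses the nucleus strongly
(pressure rise). The 2×2 system for $(C, \delta)$ is solved numerically by
nested root finding through the same `realign()` code path the model uses
(`calibrate_defaults()`, residuals < 1e-4 MPa); the shipped
`motion_segment()` defaults *are* that solution ($C = 1.2511$ MPa⁻¹,
$\delta = -0.2483$ mm), and `scripts/calibrate.R` re-derives them.

The effective annulus modulus is set by a stated rule rather than fitted:
$E_{af} = \sigma_{arrest} h_0 / (2r \tan 10°) = 0.662$ MPa drives the
posterior disc edge in the stiff scenario exactly to the arrest threshold
beyond the swelling prestress, so the stiff correction predicts a finite
arrested zone while the flexible correction stays everywhere inside the
threshold — the qualitative contrast the two scenarios are meant to
exhibit. The surrogate reports *axial* plate stress; whether the reference
stress maps are axial or von Mises is not stated, and at the growth plate
the axial component dominates the loading this model represents.

**Equilibrium.** A tether force $F$ per cable acts at a moment arm from the
axis (cable line 10 mm posterior to the disc edge — a screw-head surrogate;
this scale parameter only affects the force-angle mapping, for which no
reference value exists). `equilibrium_angle()` solves
$n_{cables} F \cdot arm = M_{disc}(\theta)$ by bracketed root finding with
a secant polish (moment residual < 1e-8 N·mm), where $M_{disc}$ integrates
station stress changes times lever arms (out-of-plane depth taken equal to
the width). The solver brackets $\theta$ below the posterior-contact limit
and reports an explicit error, naming the bracket, when the demanded moment
exceeds disc capacity. Forces large enough to correct past neutral flip the
apical angle into lordosis, and along a flexible-axis load schedule the NP
pressure is non-increasing.

# The growth law and longitudinal simulator

Growth responds linearly to growth-plate stress:

$$g(\sigma) = \max\{0,\; g_0 [1 + \beta(\sigma - \sigma_{hom})]\},
\qquad g \equiv 0 \text{ for } \sigma \le -\sigma_{arrest},$$

with $\sigma_{hom} = -p_0 = -0.15$ MPa and $\sigma_{arrest} = 0.5$ MPa.
The default slope $\beta = 1/(\sigma_{arrest} + \sigma_{hom}) =
2.857$ MPa⁻¹ is the unique choice for which the linear law reaches zero
exactly at the arrest threshold, keeping the law continuous; a
discontinuous clamp would create artificial jumps in predicted %GM. The
threshold is a reported experimental value; the slope is not, so continuity
is the principled default. In the simulator the law scales a spatially
varying baseline profile (each station's baseline rate playing the role of
$g_0$), so untethered anisotropy and stress modulation compose
multiplicatively.

`simulate_tethering()` advances daily (explicit Euler, dt = 1 day;
half-stepping changes the day-14 Cobb angle by well under 0.1°, as the
rates involved are ~10² µm/day against mm-scale geometry). Per level and
per step:

1. solve the elastic equilibrium correction for the current cable force;
2. creep the disc wedge toward it (time constant 4 days — immediate
   elastic correction is partial, as in the serial radiographs);
3. relax the disc *rest* wedge toward the held shape (stress relaxation,
   time constant 7 days);
4. evaluate the stress profile at the current elastic deflection and the
   modulated growth field;
5. grow both facing physes, incrementing the vertebral wedge by
   $\operatorname{atan}[(\Delta h_{post} - \Delta h_{ant}) / \mathrm{width}]$;
6. update the cable force from construct stretch,
   $F \leftarrow \max(0, F + k_c\,\Delta path)$ (default $k_c$ = 5 N/mm):
   the path shortens as the wedge corrects and lengthens as the posterior
   physes grow.

The disc stress-relaxation step deserves emphasis, because it is a model
hypothesis, not an observation. With a purely elastic disc, whatever force
holds the correction persists, and so would the stress asymmetry and the
%GM difference between tension arms. With relaxation, the restoring moment
the cable must balance decays, the force decays in both arms toward similar
residual values, and the instantaneous %GM difference between high and low
tension shrinks — the emergent biphasic behavior: early load-*dependent*
correction (the high-tension arm corrects faster in the first two weeks),
late load-*independent* correction (near-equal slopes thereafter). A
physeal adaptation mechanism (the growth law itself habituating to load)
could produce the same signature; the package deliberately implements only
the mechanical account, and the two cannot be distinguished by these
outputs alone. Trajectory *magnitudes* (late overcorrection depth, absolute
untreated progression) are not calibrated — vertebra count, age-dependent
rate decline and junctional behavior are outside the model — so the
simulator's contract is the property level: monotone untreated progression
from 44.2° under the observed −10% baseline asymmetry (the Table-derived
anterior 174 / posterior 191 / mean 178 ratio), biphasic correction, and
decaying tether force.

The untreated scenario uses the 65 µm/day rate observed over the 2-5 month
progression window; tethered scenarios use the 178 µm/day peri-operative
rate. Four identical levels with a 10° disc wedge and 1.05° vertebral wedge
reproduce the 44.2° starting Cobb; Cobb is always summed within the
simulated (instrumented) span.

# Numerical conventions and problem sizes

* Units: mm, N, MPa, radians internally; kPa and degrees at every I/O
  boundary, converted in one place.
* Sign conventions: tension-positive stress, kyphotic-positive wedge,
  $x = 0$ at the anterior (concave) edge, positive correction reduces
  kyphosis.
* Quadrature: the NP volume integral uses a 201-point trapezoid on the
  footprint (exact for the affine field, and verified against the
  closed-form integral to < 0.1%); regional means are station means,
  verified against dense-grid integration oracles to < 1e-6 relative.
* Degenerate inputs: zero labeling interval, non-positive mean rates,
  empty regions, disc-height closure and unreachable equilibria all raise
  named errors; zero-variance t-test comparisons are handled explicitly.
* Test and replication sizes (package choices): recovery suites use 1000
  replicate cohorts per arm (4000-5000 animals, ~30 s); the bundled
  `cmd_replicate()` driver uses 300 cohorts per arm by default and
  completes in about a minute.

# Known limitations

The mechanics is sagittal-plane and quasi-static: no coronal/axial
coupling, no poroelastic creep of the nucleus, no screw-bone interface
mechanics, and the stiff/flexible dichotomy is represented by the axis
location rather than by a continuum of disc stiffnesses. The growth law is
linear with a hard arrest threshold; real physes show saturating and
time-dependent responses. The generator's noise model is uncorrelated
Normal noise. These choices match the scope of the quantities the package
is designed to reproduce — regional growth statistics, the three calibrated
pressures, and figure-level qualitative behavior — and should be revisited
before any quantitative extrapolation beyond them.
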