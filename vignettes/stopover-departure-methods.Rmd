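---
title: "Models and methods behind stopdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopdep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopdep)
```

`stopdep` analyses the departure decisions of radio-tagged songbirds at a
migratory stopover site: whether a bird resumes migration on a given night,
when within the night it takes off, and in which direction — and how each
decision relates to the bird's energy stores. This vignette documents the
models, the tunable parameters, the numerical choices, and the places where
the underlying field methodology left the design genuinely open.

## Energy stores

Lean (fat-free) body mass is predicted from maximum wing length by a
species- and pectoral-muscle-score-specific linear calibration; the default
registry (`lean_mass_equations()`) covers common redstarts with muscle
score 2 (6.69 g + 0.08 g/mm × wing) and European robins with scores 2
(2.48 + 0.17 × wing) and 3 (2.77 + 0.17 × wing), the only combinations
occurring in autumn migrants at the site the package was built around.
Requests outside the registry raise an error naming the missing equation
rather than extrapolating — a redstart scored 3 is not a robin scored 3.

Energy stores are the relative fuel load e = (body mass − lean)/lean.
Being a ratio, e is scale-free and can be negative (a bird below its
predicted fat-free mass). Stores enter regression models as within-species
z-scores (`scale_within_species()`, n − 1 denominator), which makes the
store effect comparable across species of different structural size; the
scaling errors on zero within-species variance rather than silently
producing zeros. Note one unit pitfall in the surrounding literature:
relative fuel loads are fractions (0.05, 0.15, …) even where prose styles
them as percentages; the package reports fractions throughout.

## Departure events in the telemetry record

The receiver array is modelled as a single site with antennas aligned
radially (default spacing 30°). A departure has a characteristic signature:
a rapid surge of received signal strength on most antennas when the bird
becomes airborne, a maximum near take-off, then a decline on fewer and
fewer antennas until the signal is permanently lost.

`segment_departure_event()` operationalises this with four parameters
(`departure_params()`):

* `rise_dB` (default 10 dB) — the across-antenna maximum signal must rise
  by at least this much above its trailing baseline to count as a surge.
* `rise_window_min` (10 min) — the lag between the baseline window and the
  point under test; also the dwell used to merge surge runs separated only
  by noise flicker around the threshold crossing.
* `baseline_win_min` (30 min) — length of the trailing window whose median
  is the baseline. A median is used so that the surge itself, or isolated
  dropouts, cannot drag the baseline.
* `gap_min` (30 min) — a silence at least this long after the surge counts
  as permanent signal loss; later pings would terminate the event early.

The event window was left undefined by the field protocol, so the package
defines it: `event_start` is the final (terminal) surge onset,
`event_end` the last detection. When several surges exist, the final one is
the departure — earlier ones are aborted take-offs or fly-bys. Take-off
time is the single highest signal strength in the window, with ties broken
to the earliest instant, deterministically. A stream that simply ceases
without a surge yields `no_event_found`; in the motivating study this was
the fate of 5 of 40 tagged birds, and the same behaviour falls out of the
simulator's non-departing birds.

### Departure bearing

`estimate_bearing()` computes a weighted circular mean of the boresight
bearings of the antennas receiving the signal, with three rules:

* only detections in the **second half** of the event window are used
  (back- and side-lobe hits concentrate around take-off). "Half" is
  measured on the time axis from `event_start`, not on detection counts —
  the alternative left edge (take-off time) differs only when the onset
  and the peak are far apart, and is easy to probe by passing a modified
  event.
* the weight is a linear ramp in temporal proximity to the last detection,
  w_i = (t_i − t_mid)/(t_last − t_mid) ∈ [0, 1]. No functional form was
  prescribed for "weighted by temporal proximity"; the linear ramp is the
  simplest monotone choice and is isolated in one place so alternatives
  can be swapped in. If the only detection sits exactly at the midpoint
  (all weights zero) the estimator falls back to the unweighted bearing.
* quality control: the bearing is discarded (`NA` plus a flag) when the
  signal is lost less than `min_event_min` (3 min) after take-off
  (`short_event`), or when no antenna pointing within half the array
  spacing (±15° for a 30° array) of the computed bearing recorded anything
  during the event (`pivotal_antenna_missing`). The ±spacing/2 tolerance
  is the package's operationalisation of "pivotal antennas"; no tolerance
  was stated in the field protocol.

The estimator is rotation-equivariant and reduces to the plain circular
mean under equal weights; both properties are tested, and the whole
computation is checked against a brute-force vector sum on random small
events to 1e−9 degrees.

`minimum_stopover()` counts calendar days from capture day to departure
night inclusively (capture-night departure = 1), assigning after-midnight
take-offs to the previous evening's night by a noon-to-noon convention in
UTC. All timestamps are UTC internally; local time appears only in
formatting.

## Solar timing

`sun_events()` implements the NOAA solar position algorithm with the
standard "official" zenith of 90.833° (atmospheric refraction plus solar
radius), matching published sunrise/sunset tables to within about two
minutes; the test suite pins Helgoland dates against values frozen from an
independent implementation of the USNO almanac algorithm. The zenith is a
parameter: whether historical "proportion of night" values were computed
from official or astronomical night is unknowable from the outside, so the
convention is explicit and adjustable. `night_timing()` expresses a
take-off as minutes after sunset and as proportion of night
(minutes/night length), which normalises for seasonal night-length change;
the two outputs satisfy minutes = proportion × length to 1e−9 and daytime
instants are flagged `diurnal` with an undefined proportion. Polar
latitudes are rejected rather than approximated.

Weather is matched per day at the full hour nearest the computed sunset
(`attach_weather()`), falling back to the nearest row within ±3 h and
flagging the day missing otherwise. Wind directions stay meteorological
(blowing *from*); the blowing-toward direction is provided for plots.

## Circular statistics

Angles are degrees at every interface and radians only inside. The
Rayleigh test of uniformity uses the refined approximation
p = exp(√(1 + 4n + 4(n² − R²)) − (1 + 2n)) with R = nρ, the form used by
the standard circular-statistics packages; p is clamped away from exactly
zero, because the approximation is a tail bound, not a point mass — a
sample with ρ = 1 at n = 6 has a small positive p, and printing 0 would
misstate it. Mean directions are conventionally only *reported* when the
Rayleigh test rejects uniformity; `run_study()` computes them always and
carries a `mean_reported` flag rather than suppressing numbers.

Watson's two-sample U² is computed from the pooled circular order, with
tied values processed as one block at their common position (mid-position
treatment) and a warning, since the statistic's null distribution assumes
continuity. The p-value is reported as a bracket from the standard
large-sample critical-value table (0.152/0.187/0.268/0.385 for
0.10/0.05/0.01/0.001), with an optional seeded permutation p for users who
want a point estimate.

The circular–linear correlation is built from the three Pearson
correlations of x with cos θ and sin θ; its p-value is a randomization
estimate in which each replicate draws, **with replacement and
independently**, a resample of the angles and a resample of the linear
values. Independent resampling is the only scheme whose null is "no
association", which is what the test is for; a joint resample would
preserve the pairing and test nothing. The replicate count (default
10,000) and seed are parameters, p is the plain fraction of replicates
exceeding the observed coefficient (no add-one correction), and with a
fixed seed the value is exactly reproducible. Wind direction versus
departure direction is an angle–angle question, so the package also
provides the Jammalamadaka–SenGupta circular–circular coefficient
(`circ_circ_cor()`, two-sided on |r|) and uses it for that contrast.

## Beta regression

Nocturnal departure timing as a proportion of the night lives strictly
inside (0, 1), which is exactly the support of the beta distribution;
`beta_reg()` fits y_i ~ Beta(μ_iφ, (1 − μ_i)φ) with logit(μ_i) = x_i'β and
constant precision φ by maximum likelihood. Numerical choices:

* parameterisation (β, log φ), so the optimiser works unconstrained;
* warm start from least squares on logit(y), with a method-of-moments φ
  floored at 1;
* BFGS with the analytic gradient, relative tolerance 1e−14, one polishing
  restart if the gradient norm exceeds 1e−8 × |log-likelihood|, and a hard
  error (never a silent result) if it still exceeds 1e−4 ×;
* standard errors from the observed information at the optimum; the SE of
  φ by the delta method from log φ;
* pseudo-R² as the squared Pearson correlation between the fitted linear
  predictor and logit(y) — the convention of the reference beta-regression
  software, so values are comparable to published ones. It is undefined
  (NA) for an intercept-only model.

Responses on the boundary raise an instructive error: a departure at
sunset or sunrise exactly would need a different model, and genuinely
nocturnal departures cannot produce one. The fit is validated against an
independent ML implementation on a frozen fixture (agreement to ~1e−6),
by parameter recovery within 2 SE at n = 500, and by checking on simulated
data that the optimum's likelihood dominates the generating parameters'.

The surrounding models follow the conventions under which published
statistics of this kind are reproducible: two-sided p-values, no
multiple-testing correction, the reference species on the intercept with
the other species as an indicator, Mann–Whitney W as the "greater pairs"
count with exact p for small untied samples, and minutes-after-sunset
models on log10 (raw-scale residuals are right-skewed). `run_study()`
restricts every store-dependent model to first-night departers — stores
measured at capture are stale for birds that stayed and refuelled — and
asserts that restriction through the fitted n. Two reporting caveats are
surfaced rather than forced into agreement: direction sample sizes can
legitimately be smaller than cohort sizes (discarded bearings), and a
published residual degrees of freedom that conflicts with its n is
reported as computed, not copied.

## The synthetic-data generator

`sim_config()` defaults are the study conditions, chosen once: 14
redstarts (capture 2018-09-02) and 21 robins (2018-10-06) at Helgoland
(54.1833° N, 7.8833° E); wing length normal (CR 80 ± 2 mm, ER
72.5 ± 1.5 mm, rounded to 0.5 mm); muscle scores 2 (and 3 for robins,
p = 0.4); energy stores uniform on [−0.05, 0.2] of lean mass; first-night
departure logistic on scaled stores with intercepts logit(6/14) and
logit(7/21) and slopes 1.5 (CR) and 0 (ER) — the store effect present only
in the redstarts; stopovers of stayers 1 + geometric(0.25) extra nights
capped at 17 days; timing from the beta model with coefficients −1.20
(intercept), +1.15 (robin), −0.45 (scaled stores) and precision φ = 10
(φ is not published anywhere; 10 gives a realistic within-night spread and
interior proportions); bearings von Mises at 232° (κ = 5) for redstarts
and 185° (κ = 25) for robins, concentrations consistent with resultant
lengths near 0.9 and 0.98.

Body mass is written at full precision (not the 0.1 g field resolution) so
that recomputing e from the table inverts the draw exactly — the 1e−12
round-trip is a test, and discretisation is the caller's decision.

The radio layer is deliberately minimal: received power
P₀ − 20·log10(d) + G(δ) + N(0, σ) with P₀ = 105 dB at 1 m, a cos^k
boresight gain in dB (10·k·log10 cos δ, k = 4) floored at −30 dB, noise
σ = 2 dB, detection threshold 20 dB, sampling every 5 s. Before take-off
the bird perches 50 m from the receiver with 20 dB extra ground
attenuation; at take-off the attenuation drops (producing the surge and
the maximum at the true take-off instant) and the bird flies a straight
line at 10 m/s along its true bearing until every antenna is below
threshold (~30 min of track). Non-departing birds emit only the
stationary phase. What this does **not** emulate: multipath, back and
side lobes beyond the gain floor, receiver saturation, tag duty cycles,
irregular burst intervals, weather-dependent propagation, or movement of
the bird on the ground. Passing the end-to-end recovery tests therefore
shows the estimator chain is correct *given the event model*, not that
real Motus data are this clean; on real streams the QC flags
(`short_event`, `pivotal_antenna_missing`, `no_event_found`) do the work.

Randomness is organised as one master seed from which a per-bird substream
seed is derived arithmetically, so cohorts are bit-reproducible and adding
birds does not perturb earlier draws; cohort-level quantities (the
within-species scaling and everything derived from it) are deterministic
functions of the draws. Degenerate configurations (a point-mass store
range, a single bird of a species) contribute a zero scaled-store effect
instead of failing.

## Problem sizes in the validation suite

The suite's simulation scales were fixed as part of the study design of
each check: binomial and monotonicity checks of the generator at n =
10,000 birds; end-to-end telemetry recovery at 100 departures (criteria:
≥ 90% of bearings within ±15°, every take-off within one 5 s sample —
the array quantises bearings to 30°, so the weighted mean across adjacent
antennas is what earns the margin); beta-regression recovery at n = 500;
the size of the randomization correlation test from 1,000 null datasets of
n = 30 with 1,000 replicates each (the p-value resolution, 0.001, is ample
for a 0.03–0.07 acceptance band); brute-force agreement checks for the
rank, exact and bearing computations over dozens of random small
instances. `scripts/acceptance.R` re-runs the headline quantities from a
command-line seed in about a minute.

## Known limitations

* Single-receiver geometry: bearings come from one site's antenna pattern;
  cross-station triangulation is out of scope.
* Signal strength is treated as a relative, monotone quantity; no
  calibration to dBm or range estimation is attempted.
* The Watson p is a bracket unless permutation is requested; the
  circular–linear p is Monte Carlo and inherits its resolution from the
  replicate count.
* Solar events assume |latitude| below the polar circles and official
  zenith; twilight phases and lunar illumination are not modelled.
* The beta regression has a constant precision φ; variable-precision
  designs would need an extended model.
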