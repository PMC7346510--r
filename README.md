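# stopdep

Stopover departure decisions of migrant songbirds from automated
radio-telemetry.

Migrating songbirds alternate flights with stopovers, and the fuel
(energy stores) a bird carries is a key driver of three decisions it
makes at a stopover: *whether* to leave on a given night, *when* within
the night to take off, and *in which direction*. `stopdep` implements
the full analysis chain used to study these decisions with a
Motus-style automated telemetry array: departure-event detection in raw
multi-antenna signal streams, fuel-load estimation from morphometrics,
sunset-referenced timing, and the circular and regression statistics
that link energy stores to the decisions — in two species with
contrasting migration strategies, the long-distance migrant common
redstart (*Phoenicurus phoenicurus*, `CR`) and the medium-distance
migrant European robin (*Erithacus rubecula*, `ER`).

## What the package computes

**Departure events.** A departure appears in the telemetry record as a
rapid surge of signal strength on most antennas (the bird leaves the
ground), a peak, and a decline into permanent signal loss. The take-off
time is the instant of the highest signal strength in the event. The
departure bearing is a weighted circular mean of the boresight
directions of the receiving antennas, using only the second half of the
event (suppressing back/side-lobe hits around take-off), each detection
weighted by its temporal proximity to the last detection,
w_i = (t_i − t_mid)/(t_last − t_mid). Bearings from events losing
signal < 3 min after take-off, or without coverage by a pivotal antenna
(one aligned within half the array spacing of the result), are
discarded with QC flags.

**Energy stores.** Lean body mass is predicted from wing length per
species × muscle-score calibration (e.g. redstart, score 2:
6.69 g + 0.08 g/mm × wing), and energy stores are the relative fuel
load e = (body mass − lean)/lean, a dimensionless fraction that can be
negative.

**Timing.** A built-in NOAA solar calculator (zenith 90.833°) turns
each take-off into minutes after sunset and the proportion of night
elapsed, which normalises for seasonal night-length change.

**Inference.** Rayleigh test of uniformity
(p = exp(√(1+4n+4(n²−R²)) − (1+2n)), R = nρ), circular mean and mean
resultant length ρ, Watson's two-sample U² test, circular–linear and
circular–circular correlations with 10,000-replicate randomization
p-values, maximum-likelihood beta regression on proportion of night
(logit mean link, constant precision φ), normal linear models on log10
minutes after sunset, Mann–Whitney U and Fisher's exact tests.
`run_study()` chains everything into one report; models with an
energy-store term are restricted to first-night departers because
stores change over a stopover.

**Synthetic ground truth.** `sim_config()` / `simulate_cohort()` /
`simulate_detections()` generate bird cohorts and raw antenna streams
under a known behavioural model (study-sized defaults: 14 redstarts,
21 robins, stores in [−0.05, 0.2], a store effect on first-night
departure in the redstarts only, beta-model timing, von Mises
bearings), so every stage is testable against known truth.

## Worked example

```r
library(stopdep)

# fuel load of a redstart: muscle score 2, wing 81.5 mm, body mass 15.3 g
lean <- lean_body_mass("CR", 2, 81.5)
e    <- energy_stores(15.3, lean)
cat("lean =", lean, "g; energy stores =", round(e, 3), "\n")
#> lean = 13.21 g; energy stores = 0.158

# simulate the study conditions, detect every departure from the raw stream
cfg    <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
stream <- simulate_detections(cohort$truth, cfg)
events <- detect_departures(stream, sim_antennas(cfg))
truth  <- cohort$truth[match(events$tag_id, cohort$truth$tag_id), ]
err    <- abs((events$bearing - truth$bearing + 180) %% 360 - 180)
cat("departure events:", sum(!is.na(events$take_off_time)), "of", nrow(events), "\n")
#> departure events: 35 of 35
cat("median bearing error:", round(median(err, na.rm = TRUE), 1), "deg\n")
#> median bearing error: 1.1 deg

report <- run_study(cohort$birds, circ_reps = 1000, seed = 1)
report
```

The report prints every statistic with its sample size; the excerpt
below is the first-night beta regression (the generator's coefficients
are intercept −1.20, species +1.15, stores −0.45, so the fitted values
sit within sampling error of truth, and the negative store slope means
fatter birds take off earlier in the night):

```
-- Beta regression, proportion of night, first night --
Beta regression (logit mean link, ML), n = 17

              Estimate Std. Error z value  Pr(>|z|)
(Intercept)   -1.17089    0.26698 -4.3857 1.156e-05 ***
SpeciesER      1.03890    0.31381  3.3106 0.0009311 ***
stores_scaled -0.60820    0.17227 -3.5305 0.0004148 ***

Precision phi = 12.63 (SE 4.24 )
pseudo-R2 = 0.644  logLik = 13.4917

-- Departure directions --
CR_all             rho = 0.94, n = 14, Rayleigh p = 6.067e-08, mean = 238 deg
ER_all             rho = 0.98, n = 21, Rayleigh p = 9.702e-14, mean = 181 deg
Watson two-sample (all birds): U2 = 0.705, p < 0.001
```

`report_json(report, "report.json")` writes the same content as JSON.
A thin command-line front end with `detect`, `run-study`, `simulate`
and `circstat` subcommands is installed at
`system.file("cli", "stopdep", package = "stopdep")`.

Applying the pipeline to the real study requires the study's raw
capture/departure table; `read_bird_table()` accepts its column naming
(including the historical misspelling `dep.realtive.night`), and
`run_study()` reproduces the published statistics from it. Place such a
file at `inst/extdata/table_s1.csv` before installing to activate the
corresponding acceptance test.

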