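Package: stopdep
Title: Stopover Departure Decisions from Automated Radio-Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the departure decisions of songbirds at
    migratory stopover sites with automated radio-telemetry (Motus-style)
    arrays. Detects nocturnal departure events in multi-antenna signal
    streams and estimates take-off time and a weighted circular-mean
    departure bearing with quality-control rules; estimates lean body mass
    and relative energy stores (fuel load) from species, muscle score and
    wing length; expresses departures as minutes after sunset and
    proportion of the night via a built-in solar calculator; and provides
    the circular statistics (Rayleigh test, Watson two-sample U2 test,
    circular-linear correlation with a randomization p-value) and a
    maximum-likelihood beta regression used to relate energy stores to
    the night-to-night, within-night and directional components of the
    departure decision. A synthetic-data generator produces telemetry
    streams and bird cohorts with known ground truth so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
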