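Package: looptrack
Title: Loop-Migration Track Analysis with One-Way-Distance Route Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of twilight-resolution bird migration tracks from
    light-level geolocators: great-circle path geometry, stationary-period
    merging and itinerancy classification, per-episode migration features
    (path length, straightness, duration, speed), the One-Way-Distance
    (OWD) route-similarity metric, and permutation-based inference for
    carry-over effects and route-consistency comparisons. Includes a
    seeded generator of synthetic loop-migration cohorts for validation
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
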