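Package: geckoflux
Title: Evaporative Water Loss, Thermal Preference and Thermo-Hydroregulation
    Analysis for Small Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computation chain for seasonal ecophysiology studies of small
    ectotherms such as geckos. Provides closed-form psychrometric conversions
    (saturation vapour pressure, vapour pressure and density, absolute
    humidity, vapour pressure deficit); reduction of open-flow hygrometry
    traces to resting evaporative water loss, area-specific water loss and
    total (cutaneous) resistance to water loss; geometric surface-area
    estimation from linear body measurements via a six single-ended-cylinder
    model; body-condition indices; extraction of the thermal-preference
    set-point range (central 50% of gradient body temperatures); weighted
    refuge-occupancy summaries with equal-proportion preference tests; and a
    seeded synthetic-data generator with known ground truth so the full
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
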