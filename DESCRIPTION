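Package: beeforage
Title: Foraging Energetics and Choice Analysis for Bumblebee Behavioral Event Logs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped behavioral event logs from
    central-place foraging experiments with bumblebees. Converts raw
    per-activity event streams into flower visits and drinking choices,
    computes per-trip energy intake and expenditure with in-trip mass
    updating, evaluates the two classical foraging currencies (rate of
    energy return and energetic efficiency), summarises them in windows
    of ten drinking visits, estimates counterfactual energetics under
    alternative nectar-concentration assignments, fits binomial mixed
    models to choice proportions, and runs randomization tests on
    final-window choice proportions. Includes an agent-based simulator
    that generates complete synthetic experiments with known ground
    truth, and a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
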