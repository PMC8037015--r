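Package: hbttc
Title: Human-Biota Thresholds of Toxicological Concern for Freshwater Chemicals
Version: 0.1.0
Authors@R:
    person("hbttc", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives One Health screening thresholds for organic chemicals in
    freshwater. Aggregates acute and chronic aquatic toxicity endpoints into
    predicted no-effect concentrations (PNECs) via assessment-factor rules,
    estimates per-class ecological thresholds (eco-TTCs) as fifth percentiles
    of log10 PNEC distributions under empirical, normal and logistic
    estimators, translates human toxicological standards (Cramer-class TTC
    doses, NOAELs, ADI/TDI/RfD/benchmark doses, oral slope factors) into
    drinking-water quality standards, and combines the ecological and human
    branches by a minimum rule into generic and compound-specific
    Human-Biota TTCs. Includes a synthetic-data generator with known ground
    truth and a command-line interface for batch CSV processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
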