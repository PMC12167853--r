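Package: eabsim
Title: Bioeconomic Simulation of Late-Stage Emerald Ash Borer Management
Version: 0.1.0
Authors@R:
    person("Urban Forest Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic cohort-based bioeconomic simulator for managing
    remnant urban ash (Fraxinus) populations under late-stage emerald ash
    borer (Agrilus planipennis) infestation. Implements annual-timestep tree
    demography with integer (ceiling) cohort accounting, seven declarative
    management scenarios (injection, preemptive removal, replanting), CTLA
    trunk-formula appraisal, inflation-adjusted discounted cost accounting,
    objective-based scenario ranking, and grid sweeps over management
    decisions, with a YAML/JSON configuration layer, CSV writers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
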