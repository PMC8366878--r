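Package: rszentry
Title: Turbine- and Month-Specific Probability of Eagle Entry into Rotor-Swept Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spatial and temporal variation in an
    important component of bird collision risk at wind energy facilities:
    the probability that an eagle approaching within 150 m of a turbine
    subsequently enters its rotor-swept zone. Provides cylinder geometry
    for rotor-swept zones and curtailment volumes, processing of 1-Hz 3D
    flight tracks into per-approach binary entry outcomes, simulation of
    the informed-curtailment decision rule (inner-cylinder and
    time-to-collision triggers), a Bayesian two-way random-effects
    Bernoulli model fitted by an adaptive Metropolis-within-Gibbs sampler
    with Gelman-Rubin diagnostics, probability-of-direction summaries that
    classify turbines and months as safer or riskier than the facility
    average, and a synthetic-data generator so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
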