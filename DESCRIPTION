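Package: seedflux
Title: Propagule Pressure Estimation and Establishment Risk Simulation for
    Container-Borne Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the invasion risk posed by plant seeds
    hitchhiking on refrigerated shipping containers arriving at a seaport.
    Estimates total seasonal seed influx from biweekly interception samples
    by K-nearest-neighbours regression over sampling dates, tabulates
    germination and post-transplant survivorship rates from trial records,
    and runs a process-based mean-field simulation of population
    establishment in port greenspaces under varying escape and survival
    rates, including deterministic-expectation and stochastic modes,
    parameter sweeps and stage-flow accounting. A synthetic-data generator
    emulates seasonal arrival schedules, overdispersed per-container seed
    counts and binomial trial outcomes with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
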