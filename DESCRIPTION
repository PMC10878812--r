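Package: dyadsync
Title: Dyadic Motor Synchrony, Go/NoGo Behaviour and fNIRS Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interpersonal motor synchrony from 2-D pose
    keypoints with a graph-Laplacian pose-similarity score, modelling Go/NoGo
    reaction times and commission errors with hierarchical Bayesian lognormal
    and Poisson models, and estimating task-evoked cortical haemodynamics from
    continuous-wave fNIRS via the modified Beer-Lambert law, short-channel
    regression and an AR(1) GLM, with second-level multivariate inference on
    HbO/HbR amplitudes and the HbO-HbR difference statistic. Includes
    synthetic-data generators with known ground truth for every stage, so the
    full pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
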