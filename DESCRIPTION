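Package: tcatrace
Title: Isotopomer Network Modelling of 13C Label Propagation in the Krebs Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the propagation of 13C label through one turn of the
    Krebs (TCA) cycle when the label enters as [1,2-13C2]acetyl-CoA. The
    package enumerates the reachable positional isotopomers of citrate,
    alpha-ketoglutarate, succinate and malate from a data-driven
    atom-transition table, builds the alpha-parameterised stochastic
    transition matrix over that state space, iterates it to isotopic steady
    state, collapses positional isotopomers to mass-isotopologue
    distributions, and fits the labelled acetyl-CoA fraction alpha to
    measured LC-MS peak-area tables by total-variation discrepancy
    minimisation, converting alpha to a percent substrate contribution.
    Includes a molecule-level Monte-Carlo simulator as an independent
    stochastic cross-check and a synthetic peak-area generator for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
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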