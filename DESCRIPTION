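Package: valsyn
Title: Efficient Value Synthesis and Range Adaptation in Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models gamble valuation as a two-layer bounded-response neural
    network that synthesizes value from prospective gains and losses, and
    implements the anti-Hebbian infomax plasticity rule under which the network
    adapts its attribute-to-integration connections to the spanned ranges of
    gains and losses. Provides Monte-Carlo harnesses for range-adaptation
    simulations, model-free behavioral analyses of accept/reject gamble data
    (choice logistic regression, loss-aversion indices, sliding-window
    dynamics), maximum-a-posteriori fitting of plastic and static network
    variants to choice series with counterfactual cross-context prediction,
    representational similarity analysis with session and delay confound
    correction, and synthetic two-group study generators emulating
    narrow/wide gain-range gamble designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
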