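Package: ovarlap
Title: Opponent-Channel Value Learning with Fast Stimulus Generalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements OVaRLAP ("Outspread Valuation for Reward Learning and
    Punishment Learning"), a SARSA-style temporal-difference learner whose
    state values are read out from a fixed layer of Gaussian radial basis
    functions through two opponent weight channels, one potentiated by
    positive prediction errors and one by negative prediction errors. The
    architecture mirrors the division of labour between D1- and D2-expressing
    striatal projection neurons and yields fast stimulus generalization
    followed by discrimination. The package also provides two comparison
    agents (tabular SARSA and a MaxPain variant with separate reward and pain
    tables), 20x20 grid-world navigation environments with painful or
    painless walls, a fast simulation engine, the full experiment protocols
    (painful navigation, relearning after pain removal, disturbed-agent
    aberrant valuation), and the summary statistics and value-map analyses
    used to characterise them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
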