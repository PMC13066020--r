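Package: spocrc
Title: Stochastic Boolean Network Simulation of Sporadic Colorectal Cancer Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic asynchronous Boolean network engine together with an
    87-node signaling model of the sporadic colorectal cancer (spoCRC) epithelial
    cell and its inflammatory micro-environment. Nodes carry activation
    probabilities ("polymorphisms"), perturbations clamp nodes ON/OFF in time
    windows, and Monte-Carlo ensembles yield per-node activation frequencies.
    Built-in pipeline stages cover inflammation protocols, CRC mutation
    panels (APC/p53 loss of function, RAS gain of function, 18q allelic loss),
    single-target knockouts of COX-inhibitor targets, and celecoxib/sulindac
    multi-target inhibition profiles, plus the normalized apoptosis-restoration
    and proliferation-inhibition effect scores. An exact Markov-chain oracle for
    small networks validates the simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
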