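Package: solvcorr
Title: Physics-Guided Graph-Network Corrections for Hydration Free Energies
Version: 0.1.0
Authors@R:
    person("Solvation", "Modeling Lab", email = "maintainer@solvcorr.example.org",
           role = c("aut", "cre"))
Description: A residual-learning pipeline for small-molecule hydration free
    energies (HFEs). A physics-based prediction (e.g. a generalized Born
    implicit-solvent estimate, or any user-supplied model) provides the bulk of
    the prediction, and a graph neural network is trained to predict its
    remaining error to experiment, so that the final estimate is physics plus a
    learned correction. The package parses FreeSolv-dialect databases, builds
    heavy-atom molecular graphs with chemistry- and physics-based features,
    implements a generalized Born polar-solvation calculator with effective
    Born radii and electrostatic size, provides stratified, extreme-HFE, and
    Bemis-Murcko scaffold data splits for out-of-distribution evaluation,
    trains seeded ensembles of graph-convolution and message-passing networks
    with early stopping, and generates fully synthetic benchmark datasets with
    a controllable, learnable physics residual.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
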