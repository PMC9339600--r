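Package: isovrnet
Title: Multi-Layer Coupled Rumor Propagation with Variation and Oyster States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Seeded Monte-Carlo simulator for rumor propagation on a coupled
    two-layer (online/offline) network with an ISOVR state space
    (Ignorant, Spreader, Variation, Oyster, Recovered). Combines a
    linear-threshold activation/extinction process with per-node normally
    distributed thresholds, bounded-confidence opinion dynamics with silence
    intervals that map continuous opinions to spreader/variation/oyster roles,
    eigenvector-centrality-weighted influence for carrier-role assignment, and
    social-reinforcement random synchronization of states between layers.
    Includes configuration handling, parameter-sweep tooling, tidy CSV/JSON
    outputs and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
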