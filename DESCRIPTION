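Package: synconsol
Title: Two-Factor Synaptic Consolidation in Recurrent Attractor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying memory consolidation in recurrent binary
    attractor networks whose synapses are products of multiple subsynaptic
    factors. Implements pattern imprinting, a replay-driven consolidation
    algorithm that maximizes each neuron's signal-to-noise ratio under
    multiplicative homeostatic scaling (inducing implicit sparsification for
    multi-factor synapses), neural- and synaptic-noise robustness assays, a
    stochastic simulator of intrinsic synaptic volatility, and trajectory
    statistics: fluctuation-scaling exponents of weight changes and the
    coefficient of variation of weight norms across time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
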