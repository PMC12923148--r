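Package: stdbalance
Type: Package
Title: Balanced Excitatory-Inhibitory Networks Stabilized by Short-Term Synaptic Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and theory for densely connected excitatory-inhibitory
    neural circuits in which short-term synaptic depression (STD) on
    excitatory-to-excitatory synapses sustains a balanced state without strong
    external drive. Provides exact in-degree random connectivity generators,
    full-network rate and leaky integrate-and-fire simulators with
    Tsodyks-Markram depression, self-consistent mean-field fixed points
    (homogeneous, asymptotic balanced, and heterogeneous Gaussian branches),
    linear stability analysis via a generalized circular law for block-sparse
    random Jacobians including the critical coupling, an iterative dynamical
    mean-field solver with self-consistent colored noise for the rate-chaos
    regime, Lyapunov-exponent regime classification, and input-correlation
    diagnostics of the balance mechanism.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
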