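Package: atpnet
Title: Metabolically Gated Spiking Networks: Slow Oscillations and Burst
    Suppression from ATP-Dependent Excitability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spatially embedded networks of leaky integrate-and-fire
    neurons whose excitability is gated by intracellular ATP, a minimal model
    of cortical dynamics under reduced cerebral metabolism. Provides the
    network constructor (uniform 2D placement, Gaussian distance-dependent
    connectivity, in-strength normalization, small-world rewiring), a fast
    second-order Runge-Kutta integrator for the coupled voltage/ATP/synaptic
    dynamics, a deterministic single-neuron mean-field reduction with
    Hann-windowed rate feedback, and an analysis suite: windowed instantaneous
    firing rates, distance-binned and mean pairwise spike-rate correlations,
    threshold ON/OFF segmentation with burst statistics, a simulated local
    field potential, and ATP-rate phase trajectories. All stages are seeded
    and reproducible from a single plain-text configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
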