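Package: granet
Title: Anatomically Constrained Spiking Network Model of the Cerebellar
    Granular Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a three-dimensional spiking network model
    of the cerebellar granular layer. The package generates anatomical
    connectivity from geometric point clouds (mossy-fiber rosette strips,
    granule-cell ascending axons and parallel fibers, Golgi-cell dendritic
    cones and axonal fields), models synaptic kinetics including a linear
    cascade approximation of glutamate diffusion, NMDA magnesium block and
    GABAergic spillover, generates mossy-fiber input with a noisy
    integrate-and-fire rate coder, advances the coupled
    granule-cell/Golgi-cell circuit with gap junctions in time, and computes
    the population statistics used to characterise granular-layer dynamics:
    oscillation spectra, synchronization indices, dynamic range of
    granule-cell activation, and shuffle-corrected cross-correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    deSolve
LinkingTo: Rcpp
Config/testthat/edition: 3
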