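Package: cpgsim
Title: Conductance-Based Neural Network Simulation with Plastic Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spreadsheet-driven simulation of conductance-based neural
    networks in the Hodgkin-Huxley tradition, aimed at small invertebrate
    circuits such as central pattern generators. Neurons are point
    compartments with gated ion channels, intracellular ion pools and
    second-messenger regulation of conductances; chemical synapses support
    facilitation (via presynaptic ion pools), depression (via a presynaptic
    resource variable) and postsynaptic voltage dependence; electrical
    synapses are ohmic gap junctions; background synaptic noise is a
    balanced pair of Poisson-driven excitatory and inhibitory conductances.
    Networks are described in a plain-text workbook with named sheets.
    Integration is by fixed-step Forward Euler, a semi-implicit
    (Crank-Nicolson) scheme, or adaptive stiff-capable solvers, all with a
    pre-recording relaxation period. Analysis tools extract burst and
    motor-pattern phase durations from spike trains and drive a
    two-parameter grid search that fits phase durations to target values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
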