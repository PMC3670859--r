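Package: atrisim
Title: Multi-Scale Simulation of Left Atrial Function in a Closed-Loop
    Cardiovascular System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter model of the cardiovascular system in
    which left-atrial and left-ventricular pressures are generated from a
    sarcomere-level contraction model (four-state troponin/cross-bridge
    kinetics driven by cosine-fitted intracellular calcium transients), coupled
    through hemispheric chamber geometry and Laplace's law to passive elastance
    chambers, a time-varying-elastance right ventricle, flow resistances and
    diode valves. Simulates the system to a periodic steady state, reproduces
    the biphasic atrial pressure wave (a/v waves), E/A transmitral filling and
    the figure-eight atrial pressure-volume loop, and runs a preload-reduction
    (simulated inferior vena cava occlusion) protocol. Includes an analysis
    layer that detects fiducial points on atrial and ventricular pressure
    traces and computes standard hemodynamic indices, plus synthetic waveform
    fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
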