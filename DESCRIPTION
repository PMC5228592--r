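Package: bgnet
Title: Spiking Network Model of Basal Ganglia Action Selection and
    Dopamine-Depleted Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A clock-driven spiking network model of the rodent basal
    ganglia. Implements quadratic integrate-and-fire neurons with
    adaptation for striatal projection neurons and fast-spiking
    interneurons, adaptive exponential integrate-and-fire neurons for
    pallidal, nigral and subthalamic populations, conductance-based
    synapses with NMDA magnesium block and Tsodyks-Markram short-term
    plasticity, a dopamine-occupancy parameter-scaling layer for
    modelling 6-OHDA lesions, fan-in connectivity with striatal spatial
    windows and embedded action channels, square-wave-modulated Poisson
    cortical drives, and the spike-train statistics (Fano factor,
    oscillation index, coherence with significance levels, phase
    relations) used to characterise beta-band pathology and action
    selection performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
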