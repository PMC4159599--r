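Package: desyncdbs
Title: Design of Energy-Efficient Desynchronizing Deep Brain Stimulation Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing locally optimal, energy-efficient extracellular
    stimuli that desynchronize a population of periodically spiking thalamic
    neurons, in the style of closed-loop deep brain stimulation. The package
    computes phase response curves of a reduced conductance-based thalamic
    neuron by the adjoint method, models the electrode-electrolyte interface
    as a double-layer/Faradaic equivalent circuit, solves an Euler-Lagrange
    two-point boundary-value problem by double-bisection shooting to maximise
    a finite-time Lyapunov exponent under energy and Faradaic-current
    penalties, and evaluates the designed waveforms against charge-balanced
    biphasic pulse trains in a stochastic electrotonically coupled network
    simulation with an event-based controller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    rlang
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
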