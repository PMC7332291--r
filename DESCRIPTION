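Package: pyloric
Title: Temperature-Robust Conductance-Based Models of the Crustacean Pyloric Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-cell conductance-based model of the crustacean
    pyloric central pattern generator (PD, LP, PY) with Arrhenius-type Q10
    temperature scaling of maximal conductances and kinetic time constants.
    Provides a fixed-step RK4 integrator over arbitrary temperature schedules,
    spike/burst feature extraction (duty cycles, burst frequencies, phase
    lags, slow-wave crossings), a multi-term landscape objective for target
    rhythms, a two-stage genetic-algorithm search over conductances and Q10
    values, an activity classifier (bursting/spiking/quiescent and triphasic
    network states), currentscape decomposition of inward and outward ionic
    currents, and perturbation protocols (temperature sweeps, hysteresis
    ramps, acute current removal, crash finding).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
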