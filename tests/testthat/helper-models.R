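# Shared fixtures built in code.

# a stable single-cell burster wired as the PD compartment (conductance
# densities of the source cell model scaled by the 0.628e-3 cm^2 compartment
# area); bursts regularly at ~0.9 Hz at 10 degC
burster_model <- function(q10 = q10_set()) {
  s <- 0.628
  pyloric_model(
    PD = channel_set(gNa = 200 * s, gCaT = 2.5 * s, gCaS = 4 * s,
                     gA = 50 * s, gKCa = 5 * s, gKd = 125 * s,
                     gH = 0.05 * s, gleak = 0, tauCa = 200),
    LP = channel_set(),
    PY = channel_set(),
    gsyn = rep(0, 7), q10 = q10, name = "pd-burster")
}

demo_model_path <- function() {
  system.file("extdata", "demo_model.yaml", package = "pyloric")
}
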