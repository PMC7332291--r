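# Channel and synapse kinetics exposed at the R level. The same closed forms
# back the C++ integrator; these entry points exist for inspection and tests.

#' Gating steady state and time constant
#'
#' Evaluates the voltage-dependent steady-state activation/inactivation and
#' time constant of one gating variable of the single-compartment STG cell
#' model. The KCa activation additionally depends on intracellular calcium
#' through the factor Ca/(Ca + 3 uM), so its steady state vanishes as Ca -> 0.
#'
#' @param channel One of `"Na"`, `"CaT"`, `"CaS"`, `"A"`, `"KCa"`, `"Kd"`,
#'   `"H"`.
#' @param gate `"m"` (activation) or `"h"` (inactivation).
#' @param v Membrane potential (mV).
#' @param ca Intracellular calcium (uM); only used by KCa.
#' @return A list with `inf` (in [0,1]) and `tau` (ms, > 0), vectorized over
#'   `v`.
#' @export
gating_steady_state <- function(channel, gate = "m", v, ca = 0.05) {
  id <- paste0(channel, ".", gate)
  g <- match(id, .gates) - 1L
  if (is.na(g)) stop("unknown channel/gate combination: ", id)
  out <- vapply(v, function(vi) .gate_inf_tau_cpp(g, vi, ca), numeric(2))
  list(inf = unname(out[1, ]), tau = unname(out[2, ]))
}

#' Calcium reversal potential from the Nernst equation
#'
#' ECa = (R T / 2F) ln(Ca_out / Ca_in), with T in kelvin; this is the only
#' place temperature enters the model other than the Q10 factors.
#'
#' @param ca_in Intracellular calcium (uM), > 0.
#' @param temperature Temperature (degC).
#' @param ca_out Extracellular calcium (uM).
#' @return ECa in mV, vectorized over `ca_in`.
#' @export
nernst_eca <- function(ca_in, temperature = 10,
                       ca_out = pyloric_constants()$ca_out) {
  if (any(ca_in <= 0)) stop("intracellular calcium must be positive")
  vapply(ca_in, .nernst_eca_cpp, numeric(1), temp_c = temperature,
         ca_out = ca_out)
}

# gating exponents (m^p) and inactivation flags per channel
.gate_p <- c(Na = 3, CaT = 3, CaS = 3, A = 3, KCa = 4, Kd = 4, H = 1, leak = 0)
.has_h <- c(Na = TRUE, CaT = TRUE, CaS = TRUE, A = TRUE, KCa = FALSE,
            Kd = FALSE, H = FALSE, leak = FALSE)

#' Instantaneous intrinsic membrane current
#'
#' Ohmic current I = g m^p h (V - E) of one channel, outward positive. The
#' calcium currents use the Nernst reversal [nernst_eca()]; Na, K-family, H,
#' and leak use the fixed reversals in [pyloric_constants()].
#'
#' @param channel Channel name (see [pyloric_constants()]).
#' @param v Membrane potential (mV).
#' @param m,h Gating variable values in [0,1] (`h` ignored for channels
#'   without inactivation).
#' @param g Maximal conductance (uS), already temperature-scaled if needed.
#' @param eca Calcium reversal potential (mV), used by CaT/CaS.
#' @return Current in nA.
#' @export
intrinsic_current <- function(channel, v, m = 1, h = 1, g, eca = NULL) {
  cst <- pyloric_constants()
  e <- switch(channel,
              Na = cst$e_na, CaT = eca, CaS = eca,
              A = cst$e_k, KCa = cst$e_k, Kd = cst$e_k,
              H = cst$e_h, leak = cst$e_leak,
              stop("unknown channel: ", channel))
  if (is.null(e)) stop("calcium currents need `eca`")
  p <- .gate_p[[channel]]
  act <- if (p == 0) 1 else m^p
  hh <- if (.has_h[[channel]]) h else 1
  g * act * hh * (v - e)
}

#' Synaptic activation steady state
#'
#' s_inf(Vpre) = 1 / (1 + exp((Vth - Vpre) / Delta)) with Vth = -35 mV and
#' Delta = 5 mV for both transmitter classes.
#'
#' @param v_pre Presynaptic membrane potential (mV).
#' @return Steady-state activation in (0, 1).
#' @export
synapse_steady_state <- function(v_pre) {
  cst <- pyloric_constants()
  1 / (1 + exp((cst$v_th_syn - v_pre) / cst$delta_syn))
}

#' Synaptic activation derivative
#'
#' ds/dt = (s_inf - s) / (tau_r + tau_s) with tau_s = (1 - s_inf)/k_minus.
#' The floor tau_r = 20 ms bounds the activation timescale as s_inf -> 1.
#' Under temperature, the whole timescale is divided by the synaptic-tau Q10
#' factor `r_tau`.
#'
#' @param s Current activation in [0,1].
#' @param v_pre Presynaptic potential (mV).
#' @param class `"glut"` or `"chol"` (sets k_minus).
#' @param r_tau Arrhenius factor for the synaptic timescale (1 at Tref).
#' @return ds/dt in 1/ms.
#' @export
synapse_derivative <- function(s, v_pre, class = c("glut", "chol"),
                               r_tau = 1) {
  class <- match.arg(class)
  cst <- pyloric_constants()
  sinf <- synapse_steady_state(v_pre)
  tau_s <- (1 - sinf) / cst$k_minus[[class]]
  (sinf - s) * r_tau / (cst$tau_r_syn + tau_s)
}

#' Synaptic current
#'
#' Is = gs s (Vpost - Es), outward positive; Es = -70 mV (glutamatergic) or
#' -80 mV (cholinergic).
#'
#' @param s Activation in [0,1].
#' @param v_post Postsynaptic potential (mV).
#' @param gs Synaptic conductance (uS).
#' @param class `"glut"` or `"chol"`.
#' @return Current in nA.
#' @export
synaptic_current <- function(s, v_post, gs, class = c("glut", "chol")) {
  class <- match.arg(class)
  gs * s * (v_post - pyloric_constants()$e_syn[[class]])
}
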