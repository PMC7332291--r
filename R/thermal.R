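# Arrhenius-type Q10 temperature scaling.

#' Arrhenius scaling factor
#'
#' R(T) = Q10^((T - Tref)/10). Conductances are multiplied by R and time
#' constants divided by R, so rates speed up with warming.
#'
#' @param q10 Fold change per 10 degC (>= 1 in this model family).
#' @param temperature Temperature (degC).
#' @param t_ref Reference temperature (degC); fixed at 10 in this model.
#' @return Dimensionless factor, 1 at `temperature = t_ref`.
#' @export
arrhenius_factor <- function(q10, temperature, t_ref = 10) {
  q10^((temperature - t_ref) / 10)
}

#' Temperature-scaled model parameters
#'
#' Applies the Q10 factors of a model at temperature T: each of the 31
#' maximal conductances is multiplied by its Arrhenius factor and each of the
#' 14 timescale groups (11 gating time constants, the calcium time constant,
#' and the two synaptic activation timescales) is divided by its factor —
#' 45 independently scaled parameter groups in total. The calcium reversal
#' potential is recomputed at T through the Nernst equation independently of
#' the Q10s.
#'
#' @param model A [pyloric_model()].
#' @param temperature Temperature (degC).
#' @param t_ref Reference temperature (degC).
#' @return A list with per-cell scaled conductances (`PD`, `LP`, `PY`, uS),
#'   scaled synaptic conductances `gsyn`, scaled calcium time constants
#'   `tauCa` (ms), the rate factors applied to the gating (`r_tau_gates`),
#'   calcium (`r_tauCa`) and synaptic (`r_tau_syn`) timescales, and the
#'   Nernst prefactor function evaluated at T.
#' @export
effective_parameters <- function(model, temperature, t_ref = 10) {
  q <- model$q10
  rg <- arrhenius_factor(q[1:8], temperature, t_ref)
  rt <- arrhenius_factor(q[9:19], temperature, t_ref)
  r_tauca <- arrhenius_factor(q[["tauCa"]], temperature, t_ref)
  r_gsyn <- arrhenius_factor(q[c("gsyn.glut", "gsyn.chol")], temperature, t_ref)
  r_tausyn <- arrhenius_factor(q[c("tausyn.glut", "tausyn.chol")],
                               temperature, t_ref)
  wiring <- synapse_table()
  scale_cell <- function(x) {
    out <- x
    out[1:8] <- x[1:8] * rg
    out[["tauCa"]] <- x[["tauCa"]] / r_tauca
    out
  }
  list(
    PD = scale_cell(model$PD), LP = scale_cell(model$LP),
    PY = scale_cell(model$PY),
    gsyn = model$gsyn * unname(r_gsyn[match(wiring$class,
                                            c("glut", "chol"))]),
    tauCa = c(PD = model$PD[["tauCa"]], LP = model$LP[["tauCa"]],
              PY = model$PY[["tauCa"]]) / r_tauca,
    r_tau_gates = setNames(unname(rt), .gates),
    r_tauCa = unname(r_tauca),
    r_tau_syn = setNames(unname(r_tausyn), c("glut", "chol")),
    eca_at = function(ca_in) nernst_eca(ca_in, temperature)
  )
}

#' Number of independently temperature-scaled parameter groups
#'
#' Enumerates the quantities the Q10 machinery rescales: 31 maximal
#' conductances (24 intrinsic + 7 synaptic) and 14 timescale groups
#' (11 gating + calcium + 2 synaptic classes), a 45-dimensional path in
#' parameter space as temperature varies.
#'
#' @return Named integer vector with `conductances`, `timescales`, `total`.
#' @export
scaled_parameter_count <- function() {
  cond <- 8L * 3L + 7L
  ts <- 11L + 1L + 2L
  c(conductances = cond, timescales = ts, total = cond + ts)
}
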