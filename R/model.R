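#' @useDynLib pyloric, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd setNames runif median approx
#' @importFrom utils head tail write.csv
NULL

# canonical naming used throughout the package ------------------------------

.channels <- c("Na", "CaT", "CaS", "A", "KCa", "Kd", "H", "leak")
.gates <- c("Na.m", "Na.h", "CaT.m", "CaT.h", "CaS.m", "CaS.h",
            "A.m", "A.h", "KCa.m", "Kd.m", "H.m")
.cells <- c("PD", "LP", "PY")
.cond_names <- paste0("g", .channels)
.cell_par_names <- c(.cond_names, "tauCa")
.syn_names <- c("PD.LP.glut", "PD.LP.chol", "PD.PY.glut", "PD.PY.chol",
                "LP.PD.glut", "LP.PY.glut", "PY.LP.glut")
.q10_names <- c(paste0("g", .channels), paste0("tau.", .gates), "tauCa",
                "gsyn.glut", "gsyn.chol", "tausyn.glut", "tausyn.chol")

#' Fixed biophysical constants of the pyloric network model
#'
#' Returns the constants that are not searched by the optimizer: membrane
#' capacitance, reversal potentials, calcium buffering parameters, and the
#' synapse kinetics shared by all models. Voltages are in mV, conductances in
#' uS, currents in nA, times in ms, and calcium concentrations in uM.
#'
#' @return A named list.
#' @export
pyloric_constants <- function() {
  list(
    capacitance = 0.628,          # nF
    e_na = 50, e_k = -80, e_h = -20, e_leak = -50,  # mV
    ca_out = 3000, ca_rest = 0.05, ca_influx = 14.96,
    v_th_syn = -35, delta_syn = 5, tau_r_syn = 20,
    k_minus = c(glut = 1 / 40, chol = 1 / 100),     # 1/ms
    e_syn = c(glut = -70, chol = -80),              # mV
    t_ref = 10,                   # degC reference temperature
    cells = .cells, channels = .channels, gates = .gates,
    synapses = .syn_names, q10_names = .q10_names
  )
}

#' Wiring of the seven pyloric synapses
#'
#' The pacemaker compartment (AB/PD, called PD here) inhibits LP and PY each
#' through one glutamatergic and one cholinergic synapse; LP inhibits PD and
#' PY, and PY inhibits LP, all glutamatergic.
#'
#' @return A data frame with one row per synapse: `pre`, `post`, `class`.
#' @export
synapse_table <- function() {
  data.frame(
    synapse = .syn_names,
    pre = .cells[c(1, 1, 1, 1, 2, 2, 3)],
    post = .cells[c(2, 2, 3, 3, 1, 3, 2)],
    class = c("glut", "chol", "glut", "chol", "glut", "glut", "glut"),
    stringsAsFactors = FALSE
  )
}

#' Intrinsic parameter set for one cell
#'
#' Bundles the eight maximal conductances (uS) and the calcium buffering time
#' constant (ms) of a single compartment.
#'
#' @param gNa,gCaT,gCaS,gA,gKCa,gKd,gH,gleak Maximal conductances (uS), >= 0.
#' @param tauCa Calcium buffering time constant (ms), > 0.
#' @return A named numeric vector of length 9.
#' @export
channel_set <- function(gNa = 0, gCaT = 0, gCaS = 0, gA = 0, gKCa = 0,
                        gKd = 0, gH = 0, gleak = 0, tauCa = 200) {
  x <- c(gNa = gNa, gCaT = gCaT, gCaS = gCaS, gA = gA, gKCa = gKCa,
         gKd = gKd, gH = gH, gleak = gleak, tauCa = tauCa)
  if (any(x[1:8] < 0)) stop("conductances must be non-negative")
  if (tauCa <= 0) stop("tauCa must be positive")
  x
}

#' Q10 temperature-sensitivity set
#'
#' The 24 Q10 values of a network model: one per intrinsic maximal conductance
#' (8), one per gating time constant (11; channels that do not inactivate have
#' no h gate), one for the calcium buffering time constant, and one
#' conductance plus one activation-timescale Q10 per synapse class
#' (glutamatergic, cholinergic). Q10 values are shared across the three cells.
#'
#' @param g Named or unnamed numeric of length 8 (conductance Q10s, in [1,2]),
#'   or a single value recycled.
#' @param tau Numeric of length 11 (gating-timescale Q10s, in [1,4]), or a
#'   single value recycled.
#' @param tauCa Q10 of the calcium time constant (timescale class, [1,4]).
#' @param gsyn Length-2 numeric (glut, chol) conductance Q10s.
#' @param tausyn Length-2 numeric (glut, chol) timescale Q10s.
#' @return An object of class `q10_set`: a named numeric vector of length 24.
#' @examples
#' q10_set()                      # temperature-insensitive (all 1)
#' q10_set(g = 1.5, tau = 2.8)    # uniform sensitivities
#' @export
q10_set <- function(g = 1, tau = 1, tauCa = 1, gsyn = 1, tausyn = 1) {
  g <- rep_len(as.numeric(g), 8)
  tau <- rep_len(as.numeric(tau), 11)
  gsyn <- rep_len(as.numeric(gsyn), 2)
  tausyn <- rep_len(as.numeric(tausyn), 2)
  q <- setNames(c(g, tau, tauCa, gsyn, tausyn), .q10_names)
  validate_q10_set(q)
  structure(q, class = "q10_set")
}

validate_q10_set <- function(q) {
  if (length(q) != 24) stop("a Q10 set has exactly 24 entries")
  gidx <- c(1:8, 21:22)   # conductance-class Q10s
  tidx <- c(9:20, 23:24)  # timescale-class Q10s (tauCa included)
  if (any(q[gidx] < 1 - 1e-12) || any(q[gidx] > 2 + 1e-12))
    stop("conductance Q10s must lie in [1, 2]")
  if (any(q[tidx] < 1 - 1e-12) || any(q[tidx] > 4 + 1e-12))
    stop("timescale Q10s must lie in [1, 4]")
  invisible(q)
}

#' Construct a three-cell pyloric network model
#'
#' A model is fully specified by 31 maximal conductances (8 intrinsic per cell
#' plus 7 synaptic), three calcium time constants, and 24 Q10 temperature
#' sensitivities. All other constants are fixed (see [pyloric_constants()]).
#'
#' @param PD,LP,PY Intrinsic parameter sets from [channel_set()].
#' @param gsyn Named numeric of length 7 (uS), names as in [synapse_table()],
#'   or unnamed in that order.
#' @param q10 A [q10_set()].
#' @param name Optional free-form model name.
#' @return An object of class `pyloric_model`.
#' @export
pyloric_model <- function(PD, LP, PY, gsyn = numeric(7), q10 = q10_set(),
                          name = NULL) {
  cells <- list(PD = PD, LP = LP, PY = PY)
  for (cl in .cells) {
    x <- cells[[cl]]
    if (length(x) != 9)
      stop("each cell needs 9 intrinsic parameters (8 conductances + tauCa)")
    if (is.null(names(x))) names(x) <- .cell_par_names
    cells[[cl]] <- x[.cell_par_names]
    if (any(is.na(cells[[cl]]))) stop("missing or misnamed cell parameter")
    if (any(cells[[cl]][1:8] < 0)) stop("conductances must be non-negative")
    if (cells[[cl]][["tauCa"]] <= 0) stop("tauCa must be positive")
  }
  if (length(gsyn) != 7) stop("exactly 7 synaptic conductances required")
  gsyn <- setNames(as.numeric(gsyn),
                   if (is.null(names(gsyn))) .syn_names else names(gsyn))
  gsyn <- gsyn[.syn_names]
  if (any(is.na(gsyn))) stop("missing or misnamed synaptic conductance")
  if (any(gsyn < 0)) stop("synaptic conductances must be non-negative")
  validate_q10_set(q10)
  structure(list(PD = cells$PD, LP = cells$LP, PY = cells$PY,
                 gsyn = gsyn, q10 = q10, name = name),
            class = "pyloric_model")
}

# flat parameter vectors consumed by the C++ core
.gbase_vec <- function(model) {
  as.numeric(c(model$PD, model$LP, model$PY))
}

#' @export
coef.pyloric_model <- function(object, ...) {
  c(setNames(as.numeric(object$PD), paste0("PD.", .cell_par_names)),
    setNames(as.numeric(object$LP), paste0("LP.", .cell_par_names)),
    setNames(as.numeric(object$PY), paste0("PY.", .cell_par_names)),
    setNames(as.numeric(object$gsyn), paste0("gsyn.", .syn_names)),
    setNames(as.numeric(object$q10), paste0("q10.", .q10_names)))
}

#' @export
print.pyloric_model <- function(x, digits = 4, ...) {
  cat("Pyloric network model",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  m <- rbind(PD = x$PD, LP = x$LP, PY = x$PY)
  cat("Intrinsic parameters (uS; tauCa in ms):\n")
  print(round(m, digits))
  cat("Synaptic conductances (uS):\n")
  print(round(x$gsyn, 5))
  cat("Q10 range: conductances [", round(min(x$q10[c(1:8, 21:22)]), 3), ",",
      round(max(x$q10[c(1:8, 21:22)]), 3), "], timescales [",
      round(min(x$q10[c(9:20, 23:24)]), 3), ",",
      round(max(x$q10[c(9:20, 23:24)]), 3), "]\n")
  invisible(x)
}

#' @export
summary.pyloric_model <- function(object, temperature = 10, duration = 20,
                                  discard = 10, ...) {
  tr <- simulate(object, temperature = temperature, duration = duration,
                 discard = discard)
  bs <- burst_summary(tr)
  structure(list(model = object, temperature = temperature, bursts = bs,
                 network = classify_network(tr)),
            class = "summary.pyloric_model")
}

#' @export
print.summary.pyloric_model <- function(x, ...) {
  cat("Pyloric network model at", x$temperature, "degC:",
      x$network, "\n")
  tab <- do.call(rbind, lapply(.cells, function(cl) {
    b <- x$bursts[[cl]]
    data.frame(cell = cl, n_spikes = length(b$spikes),
               n_bursts = b$n_bursts,
               freq_hz = round(b$mean_fb, 3), duty = round(b$mean_dc, 3))
  }))
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# configuration file I/O (one YAML schema for model + Q10 + name)
# ---------------------------------------------------------------------------

#' Write a model to a configuration file
#'
#' Serializes the 31 maximal conductances, 3 calcium time constants, and 24
#' Q10 values to a human-readable YAML file (schema version 1). A
#' `provenance` attribute (e.g. the search seeds and budgets that produced
#' the model, as attached by [build_demo_network()]) is stored alongside and
#' restored on read.
#'
#' @param model A [pyloric_model()].
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema = "pyloric-model/1",
    name = if (is.null(model$name)) "unnamed" else model$name,
    cells = list(PD = as.list(model$PD), LP = as.list(model$LP),
                 PY = as.list(model$PY)),
    synapses = as.list(model$gsyn),
    q10 = as.list(unclass(model$q10))
  )
  if (!is.null(attr(model, "provenance")))
    obj$provenance <- attr(model, "provenance")
  yaml::write_yaml(obj, path, precision = 18)
  invisible(path)
}

#' Read a model from a configuration file
#'
#' @param path Path to a file written by [write_model()].
#' @return A [pyloric_model()].
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema) || !startsWith(obj$schema, "pyloric-model/"))
    stop("not a pyloric model configuration file")
  as_cell <- function(x) unlist(x)[.cell_par_names]
  q <- unlist(obj$q10)[.q10_names]
  m <- pyloric_model(PD = as_cell(obj$cells$PD), LP = as_cell(obj$cells$LP),
                     PY = as_cell(obj$cells$PY),
                     gsyn = unlist(obj$synapses)[.syn_names],
                     q10 = structure(q, class = "q10_set"),
                     name = obj$name)
  if (!is.null(obj$provenance)) attr(m, "provenance") <- obj$provenance
  m
}
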