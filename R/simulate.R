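# Fixed-step RK4 integration of the 46-dimensional network.

#' Canonical initial state
#'
#' All simulations start from the same state: V = -51 mV, every gating and
#' synaptic activation variable at 0, and intracellular calcium at 5 uM, in
#' each cell.
#'
#' @return Named numeric vector of length 46 (13 per cell + 7 synapses).
#' @export
initial_state <- function() {
  cell <- c(V = -51, setNames(rep(0, 11), .gates), Ca = 5)
  setNames(c(rep(unname(cell), 3), rep(0, 7)),
           c(paste(rep(.cells, each = 13), names(cell), sep = "."),
             paste0("s.", .syn_names)))
}

#' Full network derivative
#'
#' Time derivative of the 46-component state at temperature T, with all Q10
#' scaling and the Nernst calcium reversal applied. Deterministic: identical
#' inputs give bit-identical outputs.
#'
#' @param state Numeric vector of length 46 (see [initial_state()]).
#' @param model A [pyloric_model()].
#' @param temperature Temperature (degC).
#' @param pin_eca If `TRUE`, evaluate the calcium Nernst prefactor at the
#'   reference temperature instead of T (used to isolate Q10 effects).
#' @return Derivative vector of length 46 (per ms).
#' @export
network_derivatives <- function(state, model, temperature = 10,
                                pin_eca = FALSE) {
  .net_deriv_cpp(as.numeric(state), .gbase_vec(model),
                 as.numeric(model$gsyn), as.numeric(model$q10),
                 temperature, 10, if (pin_eca) 10 else temperature, NULL)
}

#' Single RK4 step
#'
#' One classical Runge-Kutta-4 update of the network state; gating and
#' synaptic variables are clamped to [0,1] afterwards.
#'
#' @inheritParams network_derivatives
#' @param dt Time step (ms).
#' @return Updated state vector of length 46.
#' @export
rk4_step <- function(state, model, temperature = 10, dt = 0.05) {
  setNames(.rk4_step_cpp(as.numeric(state), .gbase_vec(model),
                         as.numeric(model$gsyn), as.numeric(model$q10),
                         temperature, 10, temperature, dt),
           names(initial_state()))
}

# normalize a temperature argument to a schedule matrix (time ms, degC)
.temp_schedule <- function(temperature) {
  if (is.numeric(temperature) && length(temperature) == 1)
    return(matrix(c(0, temperature), 1, 2))
  m <- as.matrix(temperature)
  if (ncol(m) != 2) stop("a temperature schedule needs columns (time_ms, temp)")
  storage.mode(m) <- "double"
  m
}

# multiplier vector over the 34 scalable parameters (24 intrinsic
# conductances cell-major, 7 synaptic conductances, 3 tauCa) for a
# perturbation `id` scaled to `fraction` of its control value
conductance_scale <- function(id, fraction) {
  sc <- rep(1, 34)
  idx <- integer(0)
  if (id %in% .cond_names) {
    ch <- match(id, .cond_names)
    idx <- ch + 8 * (0:2)
  } else if (grepl("^(PD|LP|PY)\\.g", id)) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    cell <- match(parts[1], .cells)
    ch <- match(parts[2], .cond_names)
    if (is.na(cell) || is.na(ch)) stop("unknown conductance id: ", id)
    idx <- ch + 8 * (cell - 1)
  } else if (id == "gsyn") {
    idx <- 24 + 1:7
  } else if (id %in% c("gsyn.glut", "gsyn.chol")) {
    cls <- sub("gsyn.", "", id, fixed = TRUE)
    idx <- 24 + which(synapse_table()$class == cls)
  } else if (id %in% .syn_names) {
    idx <- 24 + match(id, .syn_names)
  } else {
    stop("unknown conductance id: ", id)
  }
  sc[idx] <- fraction
  sc
}

#' Simulate a pyloric network model
#'
#' Integrates the 46-dimensional network with fixed-step RK4 under a constant
#' temperature or a piecewise-linear temperature schedule, discards the
#' transient window, and returns the recorded series. The integration is
#' fully deterministic; `nsim` and `seed` are accepted for compatibility with
#' the [stats::simulate()] generic and ignored.
#'
#' @param object A [pyloric_model()].
#' @param nsim,seed Ignored (the model is deterministic).
#' @param duration Total simulated time (s).
#' @param discard Initial transient dropped from the record (s).
#' @param dt Integration step (ms).
#' @param temperature A single temperature (degC) or a 2-column matrix
#'   `(time_ms, temp)` describing a piecewise-linear schedule, evaluated at
#'   every step.
#' @param stride Record every `stride`-th step.
#' @param record `"v"` records membrane potentials only; `"full"` adds all
#'   intrinsic and synaptic currents, synaptic activations, calcium, and
#'   dV/dt.
#' @param init Initial state (defaults to [initial_state()]).
#' @param fast If `TRUE`, gating kinetics are evaluated from precomputed
#'   lookup tables (0.02 mV grid, linear interpolation) instead of the closed
#'   forms; intended for optimization workloads.
#' @param pin_eca Evaluate the Nernst prefactor at the reference temperature.
#' @param perturb Optional named list `list(id =, fraction =)` scaling one
#'   conductance (or conductance group) to `fraction` of its control value
#'   from `t_switch` seconds onward (see [acute_deletion()]).
#' @param t_switch Time (s) at which `perturb` takes effect.
#' @param ... Unused.
#' @return A `pyloric_trace`: time grid (ms), temperature, V matrix, and in
#'   full mode currents (nA, outward positive), synaptic activations,
#'   calcium, and dV/dt. Attributes record the configuration; a blow-up is
#'   reported via the `blow_time` field with the record truncated, not an
#'   error.
#' @export
simulate.pyloric_model <- function(object, nsim = 1, seed = NULL,
                                   duration = 20, discard = 10, dt = 0.05,
                                   temperature = 10, stride = 1,
                                   record = c("v", "full"),
                                   init = initial_state(), fast = FALSE,
                                   pin_eca = FALSE, perturb = NULL,
                                   t_switch = 0, ...) {
  record <- match.arg(record)
  if (duration < discard) stop("duration must be at least the discard window")
  sched <- .temp_schedule(temperature)
  gscale <- NULL
  if (!is.null(perturb))
    gscale <- conductance_scale(perturb$id, perturb$fraction)
  res <- .simulate_cpp(as.numeric(init), .gbase_vec(object),
                       as.numeric(object$gsyn), as.numeric(object$q10),
                       sched, 10, pin_eca, dt, duration * 1000,
                       discard * 1000, as.integer(stride),
                       if (record == "full") 1L else 0L, fast, gscale,
                       t_switch * 1000)
  m <- res$record
  n <- as.integer(res$n_recorded)
  if (n < nrow(m)) m <- m[seq_len(n), , drop = FALSE]
  cur_names <- c(t(outer(.cells, .channels, paste, sep = ".")))
  tr <- list(
    time = m[, 1], temperature = m[, 2],
    V = `colnames<-`(m[, 3:5, drop = FALSE], .cells),
    currents = NULL, syn_currents = NULL, s = NULL, ca = NULL, dvdt = NULL,
    blow_time = if (res$blow_time >= 0) res$blow_time else NA_real_,
    final_state = setNames(res$final_state, names(initial_state())),
    model = object
  )
  if (record == "full" && n > 0) {
    tr$currents <- `colnames<-`(m[, 6:29, drop = FALSE], cur_names)
    tr$syn_currents <- `colnames<-`(m[, 30:36, drop = FALSE], .syn_names)
    tr$s <- `colnames<-`(m[, 37:43, drop = FALSE], .syn_names)
    tr$ca <- `colnames<-`(m[, 44:46, drop = FALSE], .cells)
    tr$dvdt <- `colnames<-`(m[, 47:49, drop = FALSE], .cells)
  }
  attr(tr, "config") <- list(duration = duration, discard = discard, dt = dt,
                             stride = stride, record = record, fast = fast,
                             pin_eca = pin_eca, perturb = perturb,
                             t_switch = t_switch)
  class(tr) <- "pyloric_trace"
  tr
}

#' @export
print.pyloric_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Pyloric trace:", length(x$time), "samples,",
      format(cfg$duration - cfg$discard), "s analyzed (dt =", cfg$dt, "ms,",
      "stride", cfg$stride, ")\n")
  tr <- range(x$temperature)
  if (diff(tr) < 1e-9) cat("Temperature:", tr[1], "degC\n")
  else cat("Temperature:", tr[1], "to", tr[2], "degC\n")
  if (!is.na(x$blow_time))
    cat("NOTE: integration blew up at t =", x$blow_time, "ms\n")
  invisible(x)
}

#' @export
plot.pyloric_trace <- function(x, cells = .cells, ...) {
  op <- graphics::par(mfrow = c(length(cells), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (cl in cells) {
    graphics::plot(x$time / 1000, x$V[, cl], type = "l", xlab = "",
                   ylab = paste0(cl, " (mV)"), ...)
  }
  invisible(x)
}

#' Trace to data frame
#'
#' @param x A `pyloric_trace`.
#' @param ... Unused.
#' @return Data frame with time (ms), temperature, and recorded series.
#' @export
as.data.frame.pyloric_trace <- function(x, ...) {
  df <- data.frame(time = x$time, temperature = x$temperature,
                   x$V, check.names = FALSE)
  for (f in c("currents", "syn_currents", "s", "ca", "dvdt")) {
    if (!is.null(x[[f]])) {
      m <- x[[f]]
      colnames(m) <- paste(f, colnames(m), sep = ".")
      df <- cbind(df, m)
    }
  }
  df
}

# ---------------------------------------------------------------------------
# trace file I/O
# ---------------------------------------------------------------------------

#' Write a trace to a columnar file
#'
#' Saves the recorded series as CSV preceded by a commented YAML header that
#' records the full model (conductances and Q10s), the simulation
#' configuration, and the package version — everything needed to re-run the
#' simulation and reproduce the trace exactly.
#'
#' @param trace A `pyloric_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  cfg <- attr(trace, "config")
  hdr <- list(schema = "pyloric-trace/1",
              package_version = as.character(utils::packageVersion("pyloric")),
              config = cfg,
              model = if (!is.null(trace$model)) list(
                name = if (is.null(trace$model$name)) "unnamed"
                       else trace$model$name,
                cells = list(PD = as.list(trace$model$PD),
                             LP = as.list(trace$model$LP),
                             PY = as.list(trace$model$PY)),
                synapses = as.list(trace$model$gsyn),
                q10 = as.list(unclass(trace$model$q10))),
              blow_time = if (is.na(trace$blow_time)) "none"
                          else trace$blow_time)
  yml <- strsplit(yaml::as.yaml(hdr, precision = 18), "\n")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", yml), con)
  df <- as.data.frame(trace)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path Trace file.
#' @return A `pyloric_trace` (model and configuration restored from the
#'   header; current/state columns restored when present).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "# ")
  hdr <- yaml::yaml.load(paste(sub("^# ?", "", lines[is_hdr]),
                               collapse = "\n"))
  if (is.null(hdr$schema) || !startsWith(hdr$schema, "pyloric-trace/"))
    stop("not a pyloric trace file")
  df <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"),
                        check.names = FALSE)
  model <- if (!is.null(hdr$model)) {
    q <- unlist(hdr$model$q10)[.q10_names]
    pyloric_model(PD = unlist(hdr$model$cells$PD)[.cell_par_names],
                  LP = unlist(hdr$model$cells$LP)[.cell_par_names],
                  PY = unlist(hdr$model$cells$PY)[.cell_par_names],
                  gsyn = unlist(hdr$model$synapses)[.syn_names],
                  q10 = structure(q, class = "q10_set"),
                  name = hdr$model$name)
  }
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(df), value = TRUE)
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
    m
  }
  tr <- list(time = df$time, temperature = df$temperature,
             V = as.matrix(df[.cells]),
             currents = grab("currents"), syn_currents = grab("syn_currents"),
             s = grab("s"), ca = grab("ca"), dvdt = grab("dvdt"),
             blow_time = if (identical(hdr$blow_time, "none")) NA_real_
                         else as.numeric(hdr$blow_time),
             final_state = NULL, model = model)
  attr(tr, "config") <- hdr$config
  class(tr) <- "pyloric_trace"
  tr
}
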