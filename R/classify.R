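# Activity classification: per-cell decision tree and the network-level
# triphasic test.

.cell_labels <- c("regular bursting", "irregular bursting", "tonic spiking",
                  "irregular spiking", "single-spike bursting", "quiescent",
                  "other")

#' Classify single-cell activity
#'
#' Decision tree over spike-train statistics. With at most one interspike
#' interval the cell is quiescent (the CV is undefined, so this gate comes
#' first). A low-variability train (CV_ISI < 0.1) is spiking: tonic if
#' spikes sit within 20 ms of a slow-wave threshold crossing, otherwise
#' single-spike bursting (each spike rides its own slow wave). A variable
#' train is grouped into bursts (200 ms gap): regular bursting if duty
#' cycles and instantaneous burst frequencies are tight (CV_dc < 1,
#' CV_fb < 0.1) with positive mean duty cycle; irregular bursting if duty
#' cycles are positive but dispersed; irregular spiking when every burst is a
#' single spike (mean dc = 0); anything else, including exact ties on the CV
#' boundaries, is labelled other.
#'
#' @param v Membrane potential series (mV), or a `pyloric_trace` (with
#'   `cell`).
#' @param time Time grid (ms); ignored when `v` is a trace.
#' @param cell Cell to classify when `v` is a trace.
#' @param spike_threshold,gap,sw_threshold,sw_smooth Detector settings.
#' @param delta_max Spike-onset-to-slow-wave lag separating tonic spiking
#'   from single-spike bursting (ms).
#' @return One of "regular bursting", "irregular bursting", "tonic spiking",
#'   "irregular spiking", "single-spike bursting", "quiescent", "other".
#' @export
classify_cell <- function(v, time = NULL, cell = "PD", spike_threshold = -20,
                          gap = 200, sw_threshold = -50, sw_smooth = 50,
                          delta_max = 20) {
  if (inherits(v, "pyloric_trace")) {
    time <- v$time
    v <- v$V[, cell]
  }
  if (!length(v) || any(!is.finite(v))) return("other")
  spikes <- detect_spikes(v, time, spike_threshold)
  isi <- isi_series(spikes)
  if (length(isi$isi) <= 1) return("quiescent")
  cv_isi <- isi$cv
  if (is.na(cv_isi)) return("quiescent")
  if (cv_isi < 0.1) {
    # spiking: lag between spike onsets and slow-wave crossings
    sw <- .slow_wave_times(v, time, sw_threshold, sw_smooth)
    if (!length(sw)) return("tonic spiking")  # never leaves the slow wave up
    delta <- stats::median(vapply(spikes, function(ts) {
      prev <- sw[sw <= ts]
      if (length(prev)) ts - prev[length(prev)] else Inf
    }, numeric(1)))
    return(if (delta < delta_max) "tonic spiking" else "single-spike bursting")
  }
  if (cv_isi > 0.1) {
    b <- group_bursts(spikes, gap)
    m <- burst_metrics(b)
    if (length(m$dc) == 0) return("other")
    mean_dc <- mean(m$dc)
    cv_dc <- if (length(m$dc) >= 2 && mean_dc > 0)
      .pop_sd(m$dc) / mean_dc else 0
    cv_fb <- if (length(m$fb) >= 2) .pop_sd(m$fb) / mean(m$fb) else 0
    if (cv_dc < 1 && cv_fb < 0.1 && mean_dc > 0) return("regular bursting")
    if (mean_dc > 0 && (cv_dc > 1 || cv_fb > 0.1)) return("irregular bursting")
    if (mean_dc == 0) return("irregular spiking")
  }
  "other"
}

#' Classify network activity
#'
#' The network is triphasic when all three cells burst, their burst
#' frequencies agree within 5% of the mean, and the bursts recur in the
#' cyclic order PD, LP, PY; otherwise it is not triphasic.
#'
#' @param trace A `pyloric_trace`, or a [burst_summary()].
#' @param freq_tol Allowed fractional spread of the three burst frequencies.
#' @return `"triphasic"` or `"not triphasic"`.
#' @export
classify_network <- function(trace, freq_tol = 0.05) {
  bs <- if (inherits(trace, "burst_summary")) trace else burst_summary(trace)
  fb <- vapply(.cells, function(cl) bs[[cl]]$mean_fb, numeric(1))
  if (any(is.na(fb)) || any(fb <= 0)) return("not triphasic")
  if ((max(fb) - min(fb)) > freq_tol * mean(fb)) return("not triphasic")
  # cyclic order: each PD start is followed by LP then PY before the next PD
  pd <- bs$PD$bursts$start
  lp <- bs$LP$bursts$start
  py <- bs$PY$bursts$start
  if (length(pd) < 2) return("not triphasic")
  ok <- vapply(seq_len(length(pd) - 1), function(k) {
    t0 <- pd[k]; t1 <- pd[k + 1]
    l <- lp[lp >= t0 & lp < t1]
    p <- py[py >= t0 & py < t1]
    length(l) == 1 && length(p) == 1 && l < p
  }, logical(1))
  # demand the right order in every interior cycle; the first and last may
  # be clipped by the analysis window
  interior <- if (length(ok) > 2) ok[2:(length(ok) - 1)] else ok
  if (all(interior) && sum(!ok) <= 1) "triphasic" else "not triphasic"
}

#' Response grid for graded conductance removal
#'
#' Scales one conductance (in all cells, or one synapse class) to 100, 75,
#' 50, 25, and 0% of its control value, simulates at a fixed temperature, and
#' classifies each cell and the network. The 100% row is the control
#' condition.
#'
#' @param model A [pyloric_model()].
#' @param conductance Conductance id, e.g. `"gNa"`, `"gA"`, `"gsyn.glut"`.
#' @param temperature Simulation temperature (degC).
#' @param levels Removal levels (fractions of control, decreasing).
#' @param duration,discard,dt Simulation protocol.
#' @param fast Use tabulated kinetics.
#' @return A `response_grid`: data frame with one row per level and columns
#'   `level`, `PD`, `LP`, `PY`, `NET`; blow-ups are labelled `other`.
#' @export
response_grid <- function(model, conductance, temperature = 10,
                          levels = c(1, 0.75, 0.5, 0.25, 0),
                          duration = 20, discard = 10, dt = 0.05,
                          fast = FALSE) {
  rows <- lapply(levels, function(f) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = temperature, fast = fast,
                   perturb = list(id = conductance, fraction = f))
    if (!is.na(tr$blow_time) || length(tr$time) == 0) {
      data.frame(level = f, PD = "other", LP = "other", PY = "other",
                 NET = "not triphasic", stringsAsFactors = FALSE)
    } else {
      data.frame(level = f,
                 PD = classify_cell(tr, cell = "PD"),
                 LP = classify_cell(tr, cell = "LP"),
                 PY = classify_cell(tr, cell = "PY"),
                 NET = classify_network(tr), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "conductance") <- conductance
  attr(out, "temperature") <- temperature
  class(out) <- c("response_grid", "data.frame")
  out
}

#' Compare complete-removal responses across temperatures
#'
#' Compares the complete-removal (0%) rows of two response grids, typically
#' computed at 10 and 25 degC: the responses are the same only when every
#' label (PD, LP, PY, and the network) agrees — complete removal of the H
#' current, for instance, tends to produce equivalent quiescent states at
#' both temperatures, while calcium-current removals often do not.
#' Symmetric in its arguments.
#'
#' @param grid1,grid2 Response grids from [response_grid()] for the same
#'   conductance.
#' @return `"same"` or `"different"`.
#' @export
compare_removal_across_temperatures <- function(grid1, grid2) {
  cols <- c("PD", "LP", "PY", "NET")
  r1 <- unlist(grid1[which.min(grid1$level), cols])
  r2 <- unlist(grid2[which.min(grid2$level), cols])
  if (identical(unname(r1), unname(r2))) "same" else "different"
}
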