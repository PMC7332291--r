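# Experiment protocols: temperature sweeps, hysteresis ramps, acute current
# deletion, crash finding. All protocols drive the single simulate() entry
# point; none has its own integrator.

#' Piecewise-linear temperature ramp schedule
#'
#' Builds a schedule matrix for [simulate.pyloric_model()]. Presets:
#' `ramp_up_down(10, 35, 30)` is the 30 min up / 30 min down hysteresis
#' protocol; `ramp_up_down(10, 25, 60, down = FALSE)` the 60 min working-range
#' ramp.
#'
#' @param from,to Start and peak temperatures (degC).
#' @param duration_min One-way ramp duration (minutes).
#' @param down Append the symmetric down-ramp.
#' @return A 2- or 3-row matrix `(time_ms, temp)`.
#' @export
ramp_up_down <- function(from = 10, to = 35, duration_min = 30, down = TRUE) {
  ms <- duration_min * 60 * 1000
  if (down) matrix(c(0, ms, 2 * ms, from, to, from), ncol = 2)
  else matrix(c(0, ms, from, to), ncol = 2)
}

#' Steady-state burst summaries across a temperature grid
#'
#' Simulates the model at each temperature (30 s runs with a 10 s discard by
#' default, matching the working-range characterization at 16 temperatures in
#' [10, 25] degC) and tabulates frequency, duty cycle, and phase lags.
#' Failures at single temperatures are recorded and the sweep continues.
#'
#' @param model A [pyloric_model()].
#' @param temperatures Temperature grid (degC).
#' @param duration,discard,dt Per-temperature protocol (s, s, ms).
#' @param fast Use tabulated kinetics.
#' @return A data frame, one row per temperature: mean burst frequency and
#'   duty cycle per cell, phase lags, network label, and a `failed` flag.
#' @export
temperature_sweep <- function(model, temperatures = seq(10, 25,
                                                        length.out = 16),
                              duration = 30, discard = 10, dt = 0.05,
                              fast = FALSE) {
  rows <- lapply(temperatures, function(T) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = T, fast = fast)
    if (!is.na(tr$blow_time) || length(tr$time) == 0) {
      return(data.frame(temperature = T, fb.PD = NA, fb.LP = NA, fb.PY = NA,
                        dc.PD = NA, dc.LP = NA, dc.PY = NA,
                        lag.PD.LP = NA, lag.PD.PY = NA,
                        network = "not triphasic", failed = TRUE))
    }
    bs <- burst_summary(tr)
    data.frame(temperature = T,
               fb.PD = bs$PD$mean_fb, fb.LP = bs$LP$mean_fb,
               fb.PY = bs$PY$mean_fb,
               dc.PD = bs$PD$mean_dc, dc.LP = bs$LP$mean_dc,
               dc.PY = bs$PY$mean_dc,
               lag.PD.LP = bs$lags[["PD.LP"]], lag.PD.PY = bs$lags[["PD.PY"]],
               network = classify_network(bs), failed = FALSE)
  })
  do.call(rbind, rows)
}

#' Temperature ramp with hysteresis detection
#'
#' Runs an up-down temperature ramp and compares where spiking ceases on the
#' way up with where it resumes on the way down. Cessation is the temperature
#' of the last spike before a sustained quiescent window (5 s) on the
#' up-ramp; resumption is the temperature of the first spike on the down-ramp
#' after the quiescent period. A resumption temperature below the cessation
#' temperature means the quiescent and rhythmic states coexist over that
#' range — multistability.
#'
#' @param model A [pyloric_model()].
#' @param ramp Schedule from [ramp_up_down()] (must include a down-ramp).
#' @param cell Cell whose spikes are monitored.
#' @param quiet_window Spike-free window defining quiescence (s).
#' @param dt,stride Integration step (ms) and record stride.
#' @param fast Use tabulated kinetics.
#' @return A `hysteresis_report`: `cessation` and `resumption` temperatures
#'   (degC, `NA` when the cell never goes quiet), `multistable` flag, spike
#'   times/temperatures, and the `applicable` flag.
#' @export
ramp_with_hysteresis <- function(model, ramp = ramp_up_down(), cell = "PD",
                                 quiet_window = 5, dt = 0.05, stride = 20,
                                 fast = FALSE) {
  total_s <- max(ramp[, 1]) / 1000
  tr <- simulate(model, duration = total_s, discard = 0, dt = dt,
                 temperature = ramp, stride = stride, fast = fast)
  spikes <- detect_spikes(tr$V[, cell], tr$time)
  t_peak <- ramp[which.max(ramp[, 2]), 1]
  qw <- quiet_window * 1000
  up <- spikes[spikes <= t_peak]
  down <- spikes[spikes > t_peak]
  gaps <- diff(c(up, t_peak))
  cease_i <- which(gaps >= qw)
  report <- list(cessation = NA_real_, resumption = NA_real_,
                 multistable = FALSE, applicable = FALSE,
                 spike_times = spikes,
                 spike_temps = approx(tr$time, tr$temperature,
                                      xout = spikes)$y,
                 ramp = ramp, cell = cell)
  if (length(cease_i) && length(up)) {
    t_cease <- up[cease_i[1]]
    report$cessation <- approx(tr$time, tr$temperature, xout = t_cease)$y
    # resumption: first spike after the quiescent period began
    resume <- c(up[up > t_cease], down)
    resume <- resume[resume > t_cease + qw]
    if (length(resume)) {
      report$resumption <- approx(tr$time, tr$temperature,
                                  xout = resume[1])$y
      report$applicable <- TRUE
      # grid resolution of the temperature schedule at the record stride
      res <- abs(diff(range(ramp[, 2]))) / (t_peak / (dt * stride))
      report$multistable <- report$resumption < report$cessation - res
    }
  }
  class(report) <- "hysteresis_report"
  report
}

#' @export
print.hysteresis_report <- function(x, ...) {
  if (!x$applicable) {
    cat("Hysteresis ramp: no cessation/resumption within the ramp\n")
  } else {
    cat(sprintf(paste0("Hysteresis ramp (%s): spiking ceased at %.2f degC,",
                       " resumed at %.2f degC — %s\n"),
                x$cell, x$cessation, x$resumption,
                if (x$multistable) "multistable" else "no hysteresis"))
  }
  invisible(x)
}

#' Acute conductance deletion
#'
#' Simulates the model in control conditions and instantaneously scales one
#' conductance at the switch time, returning the trace with both segments for
#' comparison (20 s control + 20 s perturbed by default).
#'
#' @param model A [pyloric_model()].
#' @param conductance Conductance id (see [response_grid()]).
#' @param fraction Remaining fraction of the conductance after the switch
#'   (0 = complete removal).
#' @param temperature Simulation temperature (degC).
#' @param segment Length of each segment (s).
#' @param dt,stride Integration settings.
#' @param record Record mode.
#' @param fast Use tabulated kinetics.
#' @return List with the full `trace`, the switch time `t_switch` (ms), and
#'   `pre`/`post` burst summaries of the two segments.
#' @export
acute_deletion <- function(model, conductance, fraction = 0,
                           temperature = 10, segment = 20, dt = 0.05,
                           stride = 1, record = "v", fast = FALSE) {
  tr <- simulate(model, duration = 2 * segment, discard = 0, dt = dt,
                 temperature = temperature, stride = stride, record = record,
                 fast = fast,
                 perturb = list(id = conductance, fraction = fraction),
                 t_switch = segment)
  t_sw <- segment * 1000
  seg <- function(lo, hi) {
    idx <- tr$time >= lo & tr$time < hi
    sub <- list(time = tr$time[idx], temperature = tr$temperature[idx],
                V = tr$V[idx, , drop = FALSE], blow_time = tr$blow_time)
    class(sub) <- "pyloric_trace"
    attr(sub, "config") <- attr(tr, "config")
    sub
  }
  halfway <- t_sw / 2  # skip the initial transient in the control segment
  list(trace = tr, t_switch = t_sw,
       pre = burst_summary(seg(halfway, t_sw)),
       post = burst_summary(seg(t_sw, t_sw + (t_sw - halfway))))
}

#' Find the crash temperature
#'
#' Marches over a temperature range with the triphasic classifier as oracle
#' and returns the lowest temperature at which the network is no longer
#' triphasic, to the grid resolution. The model must be triphasic at the
#' range start; a model triphasic over the whole range is reported censored.
#'
#' @param model A [pyloric_model()].
#' @param t_range Search range (degC).
#' @param step Grid step (degC).
#' @param duration,discard,dt Per-temperature protocol.
#' @param fast Use tabulated kinetics.
#' @return List with `crash_temp` (`NA` when censored), `censored`, and the
#'   label table `by_temp`.
#' @export
crash_finder <- function(model, t_range = c(25, 40), step = 1,
                         duration = 20, discard = 10, dt = 0.05,
                         fast = FALSE) {
  temps <- seq(t_range[1], t_range[2], by = step)
  labels <- character(length(temps))
  crash <- NA_real_
  for (i in seq_along(temps)) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = temps[i], fast = fast)
    labels[i] <- if (!is.na(tr$blow_time)) "not triphasic"
    else classify_network(tr)
    if (labels[i] != "triphasic" && is.na(crash)) {
      crash <- temps[i]
      labels <- labels[seq_len(i)]
      temps <- temps[seq_len(i)]
      break
    }
  }
  if (!is.na(crash) && crash == t_range[1])
    warning("model is not triphasic at the start of the range")
  list(crash_temp = crash, censored = is.na(crash),
       by_temp = data.frame(temperature = temps, network = labels))
}
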