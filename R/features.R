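# Spike/burst feature extraction and the stability-discard rules.

#' Detect spikes by threshold crossing
#'
#' Spike times are upward crossings of the spike threshold, deduplicated
#' within a short refractory window. -20 mV separates full spikes from the
#' sub-threshold slow wave in this model family.
#'
#' @param v Membrane potential series (mV).
#' @param time Time grid (ms), same length as `v`.
#' @param threshold Spike threshold (mV).
#' @param refractory Minimum separation between detected spikes (ms).
#' @return Spike times (ms), possibly empty.
#' @export
detect_spikes <- function(v, time, threshold = -20, refractory = 2) {
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  st <- time[up + 1]
  if (length(st) > 1) {
    # sequential dedup: keep a spike only if >= refractory after last kept
    last <- st[1]; keep <- logical(length(st)); keep[1] <- TRUE
    for (i in seq_along(st)[-1]) {
      if (st[i] - last >= refractory) { keep[i] <- TRUE; last <- st[i] }
    }
    st <- st[keep]
  }
  st
}

#' Group spikes into bursts
#'
#' Maximal runs of spikes whose inter-spike gaps are below the temporal
#' threshold (200 ms). Burst start/end are the first/last spike of the run.
#'
#' @param spikes Sorted spike times (ms).
#' @param gap Temporal grouping threshold (ms).
#' @return Data frame with columns `start`, `end`, `n_spikes`.
#' @export
group_bursts <- function(spikes, gap = 200) {
  if (!length(spikes))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  brk <- which(diff(spikes) >= gap)
  starts <- c(1, brk + 1)
  ends <- c(brk, length(spikes))
  data.frame(start = spikes[starts], end = spikes[ends],
             n_spikes = ends - starts + 1L)
}

#' Per-burst frequency and duty cycle
#'
#' Periods are measured burst-start to burst-start: fb_k = 1/(start_{k+1} -
#' start_k) and dc_k = (end_k - start_k)/(start_{k+1} - start_k). The last
#' burst has no following start and contributes no metric. A single-spike
#' burst has zero duration and hence zero duty cycle.
#'
#' @param bursts Data frame from [group_bursts()].
#' @return List with `fb` (Hz), `dc`, `period` (mean start-to-start, ms), all
#'   `NA`-free; `fb` and `dc` are empty when fewer than 2 bursts exist.
#' @export
burst_metrics <- function(bursts) {
  n <- nrow(bursts)
  if (n < 2)
    return(list(fb = numeric(0), dc = numeric(0), period = NA_real_))
  per <- diff(bursts$start)
  list(fb = 1000 / per,
       dc = (bursts$end[-n] - bursts$start[-n]) / per,
       period = mean(per))
}

#' Phase lags between cells
#'
#' For each PD burst start, the lag to the first subsequent LP (resp. PY)
#' burst start, averaged and expressed as a fraction of the mean PD period.
#' Unmatched trailing PD starts are dropped.
#'
#' @param pd,lp,py Burst data frames from [group_bursts()].
#' @return Named numeric `c(PD.LP =, PD.PY =)`, `NA` when a cell lacks bursts
#'   or PD has fewer than 2.
#' @export
phase_lags <- function(pd, lp, py) {
  if (nrow(pd) < 2 || nrow(lp) < 1 || nrow(py) < 1)
    return(c(PD.LP = NA_real_, PD.PY = NA_real_))
  period <- mean(diff(pd$start))
  lag_to <- function(other) {
    lags <- vapply(pd$start, function(t0) {
      nxt <- other$start[other$start >= t0]
      if (length(nxt)) nxt[1] - t0 else NA_real_
    }, numeric(1))
    mean(lags, na.rm = TRUE)
  }
  c(PD.LP = lag_to(lp) / period, PD.PY = lag_to(py) / period)
}

#' Slow-wave threshold crossings
#'
#' Counts upward crossings of the slow-wave threshold (-50 mV) of the
#' low-pass-filtered membrane potential. Smoothing (50 ms moving average)
#' removes the fast spikes so a healthy burster crosses once per burst.
#'
#' @param v Membrane potential (mV).
#' @param time Time grid (ms).
#' @param threshold Slow-wave threshold (mV).
#' @param smooth Moving-average window (ms); 0 disables smoothing.
#' @return Number of upward crossings.
#' @export
slow_wave_crossings <- function(v, time, threshold = -50, smooth = 50) {
  length(.slow_wave_times(v, time, threshold, smooth))
}

# centered moving average via cumulative sums (O(n) for any window)
.moving_average <- function(v, w) {
  if (w <= 1) return(v)
  cs <- cumsum(c(0, v))
  n <- length(v)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# times of upward slow-wave crossings (shared by the counter and the
# classifier's onset-lag measurement)
.slow_wave_times <- function(v, time, threshold = -50, smooth = 50) {
  if (length(v) < 2) return(numeric(0))
  if (smooth > 0) {
    dt <- time[2] - time[1]
    w <- max(1L, round(smooth / dt))
    v <- .moving_average(v, w)
  }
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  time[up + 1]
}

# population standard deviation; distribution spreads here describe the
# realized burst/ISI series itself, so the n (not n-1) normalization is used
# throughout: an alternating {100, 300} ISI series has CV exactly 0.5
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Interspike intervals and their coefficient of variation
#'
#' @param spikes Spike times (ms).
#' @return List with `isi` (ms) and `cv` (population sd / mean; `NA` with
#'   fewer than 2 ISIs).
#' @export
isi_series <- function(spikes) {
  isi <- diff(spikes)
  cv <- if (length(isi) >= 2) .pop_sd(isi) / mean(isi) else NA_real_
  list(isi = isi, cv = cv)
}

#' Stability-discard rule
#'
#' A solution is discarded when its rhythm is insufficiently regular:
#' std(fb) >= 0.1 mean(fb) or std(dc) >= 0.2 mean(dc) for any cell, or when
#' the metrics are undefined (fewer than 2 bursts).
#'
#' @param fb Per-burst frequencies (Hz).
#' @param dc Per-burst duty cycles.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
stability_filter <- function(fb, dc) {
  if (length(fb) < 2 || length(dc) < 1) return(FALSE)
  mfb <- mean(fb); mdc <- mean(dc)
  if (!is.finite(mfb) || mfb <= 0) return(FALSE)
  sfb <- if (length(fb) >= 2) .pop_sd(fb) else 0
  sdc <- if (length(dc) >= 2) .pop_sd(dc) else 0
  !(sfb >= 0.1 * mfb || sdc >= 0.2 * mdc)
}

#' Burst summary of a trace
#'
#' Extracts, per cell, the spike times, bursts, per-burst frequencies and
#' duty cycles, slow-wave crossing count, and the stability verdict; plus the
#' network phase lags relative to PD.
#'
#' @param trace A `pyloric_trace` from [simulate.pyloric_model()].
#' @param spike_threshold,gap,sw_threshold,sw_smooth Detector settings, see
#'   [detect_spikes()], [group_bursts()], [slow_wave_crossings()].
#' @return A `burst_summary`: per-cell lists plus `lags` (fractions of the PD
#'   period).
#' @export
burst_summary <- function(trace, spike_threshold = -20, gap = 200,
                          sw_threshold = -50, sw_smooth = 50) {
  per_cell <- lapply(.cells, function(cl) {
    sp <- detect_spikes(trace$V[, cl], trace$time, spike_threshold)
    b <- group_bursts(sp, gap)
    m <- burst_metrics(b)
    sw <- slow_wave_crossings(trace$V[, cl], trace$time, sw_threshold,
                              sw_smooth)
    list(spikes = sp, bursts = b, fb = m$fb, dc = m$dc, period = m$period,
         n_bursts = nrow(b), n_sw = sw,
         mean_fb = if (length(m$fb)) mean(m$fb) else NA_real_,
         mean_dc = if (length(m$dc)) mean(m$dc) else NA_real_,
         stable = stability_filter(m$fb, m$dc))
  })
  names(per_cell) <- .cells
  out <- per_cell
  out$lags <- phase_lags(per_cell$PD$bursts, per_cell$LP$bursts,
                         per_cell$PY$bursts)
  structure(out, class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  for (cl in .cells) {
    b <- x[[cl]]
    cat(sprintf("%s: %d spikes, %d bursts, fb = %s Hz, dc = %s, #sw = %d%s\n",
                cl, length(b$spikes), b$n_bursts,
                format(round(b$mean_fb, 3)), format(round(b$mean_dc, 3)),
                b$n_sw, if (b$stable) "" else " [unstable]"))
  }
  cat(sprintf("lags: PD-LP = %s, PD-PY = %s (fractions of PD period)\n",
              format(round(x$lags[["PD.LP"]], 3)),
              format(round(x$lags[["PD.PY"]], 3))))
  invisible(x)
}

#' Flat table of bursts
#'
#' @param summary A [burst_summary()].
#' @return Data frame, one row per burst.
#' @export
burst_table <- function(summary) {
  do.call(rbind, lapply(.cells, function(cl) {
    b <- summary[[cl]]$bursts
    if (!nrow(b)) return(NULL)
    k <- nrow(b)
    data.frame(cell = cl, burst = seq_len(k), start = b$start, end = b$end,
               n_spikes = b$n_spikes,
               fb = c(summary[[cl]]$fb, NA)[seq_len(k)],
               dc = c(summary[[cl]]$dc, NA)[seq_len(k)])
  }))
}

#' Membrane-potential distributions over temperature
#'
#' Simulates the model from identical initial conditions at each temperature
#' of a grid and histograms the membrane potential of one cell over the final
#' analysis window. The study protocol uses 101 temperatures in [10, 25]
#' degC, 30 s runs at dt = 0.001 ms, the last 10 s, and 5e5 samples per
#' temperature; those sizes are configurable because they are expensive.
#'
#' @param model A [pyloric_model()].
#' @param cell Cell to histogram.
#' @param temperatures Temperature grid (degC).
#' @param duration,discard,dt Simulation protocol (s, s, ms).
#' @param n_samples Samples retained per temperature (sets the record
#'   stride).
#' @param breaks Voltage bin edges (mV).
#' @param fast Use tabulated kinetics.
#' @return A `voltage_distribution`: list with `temperatures`, `breaks`, and
#'   a matrix `density` (temperature x bin, rows summing to 1); failed
#'   temperatures yield `NA` rows.
#' @export
voltage_distribution_sweep <- function(model, cell = "LP",
                                       temperatures = seq(10, 25,
                                                          length.out = 101),
                                       duration = 30, discard = 20,
                                       dt = 0.001, n_samples = 5e5,
                                       breaks = seq(-80, 60, by = 1),
                                       fast = FALSE) {
  n_rec_steps <- (duration - discard) * 1000 / dt
  stride <- max(1L, floor(n_rec_steps / n_samples))
  dens <- matrix(NA_real_, length(temperatures), length(breaks) - 1)
  for (i in seq_along(temperatures)) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = temperatures[i], stride = stride,
                   fast = fast)
    if (!is.na(tr$blow_time)) next  # record the gap, keep sweeping
    v <- pmin(pmax(tr$V[, cell], breaks[1]), breaks[length(breaks)])
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    dens[i, ] <- h$counts / sum(h$counts)
  }
  structure(list(temperatures = temperatures, breaks = breaks,
                 density = dens, cell = cell),
            class = "voltage_distribution")
}

#' Per-cell rhythm statistics table
#'
#' Condenses a [burst_summary()] into one row per cell: spike/burst/slow-wave
#' counts, mean and dispersion of burst frequency and duty cycle, and the
#' stability verdict — the tabular companion of [burst_table()].
#'
#' @param summary A [burst_summary()].
#' @return A data frame with one row per cell.
#' @export
burst_stats <- function(summary) {
  do.call(rbind, lapply(.cells, function(cl) {
    b <- summary[[cl]]
    data.frame(cell = cl,
               n_spikes = length(b$spikes), n_bursts = b$n_bursts,
               n_sw = b$n_sw,
               mean_fb = b$mean_fb,
               sd_fb = if (length(b$fb) >= 2) .pop_sd(b$fb) else NA_real_,
               mean_dc = b$mean_dc,
               sd_dc = if (length(b$dc) >= 2) .pop_sd(b$dc) else NA_real_,
               stable = b$stable, stringsAsFactors = FALSE)
  }))
}
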