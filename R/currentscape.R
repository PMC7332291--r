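# Currentscape decomposition: percent contribution of each current to the
# total inward and outward membrane current over time.

# currents flowing into one cell: its 8 intrinsic plus incoming synapses
.cell_current_matrix <- function(trace, cell) {
  if (is.null(trace$currents))
    stop("trace was not recorded with record = \"full\"")
  ic <- trace$currents[, paste(cell, .channels, sep = "."), drop = FALSE]
  colnames(ic) <- .channels
  wiring <- synapse_table()
  incoming <- wiring$synapse[wiring$post == cell]
  sc <- trace$syn_currents[, incoming, drop = FALSE]
  cbind(ic, sc)
}

#' Currentscape of one cell
#'
#' Classifies each current (8 intrinsic plus incoming synaptic) as inward or
#' outward by its instantaneous sign and expresses it as a percentage of the
#' total current of its sign class at each time point. A current can switch
#' class mid-cycle (leak often does). Shares within a class sum to 100%
#' wherever that class carries current; time points with no current of a
#' class are masked and reported as zero shares.
#'
#' @param trace A `pyloric_trace` recorded with `record = "full"`.
#' @param cell Cell to decompose.
#' @return A `current_shares` list: `time`, `currents` (names), `inward` and
#'   `outward` share matrices (%), `total_in`/`total_out` magnitudes (nA),
#'   and logical masks `mask_in`/`mask_out` marking defined time points.
#' @export
current_shares <- function(trace, cell = "PD") {
  m <- .cell_current_matrix(trace, cell)
  inw <- pmin(m, 0)    # inward = negative (depolarizing) currents
  outw <- pmax(m, 0)
  tot_in <- rowSums(-inw)
  tot_out <- rowSums(outw)
  mask_in <- tot_in > 0
  mask_out <- tot_out > 0
  sh_in <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  sh_out <- sh_in
  sh_in[mask_in, ] <- 100 * (-inw[mask_in, , drop = FALSE]) / tot_in[mask_in]
  sh_out[mask_out, ] <- 100 * outw[mask_out, , drop = FALSE] /
    tot_out[mask_out]
  # guard the [0, 100] contract against floating-point overshoot
  sh_in <- pmin(pmax(sh_in, 0), 100)
  sh_out <- pmin(pmax(sh_out, 0), 100)
  structure(list(time = trace$time, cell = cell, currents = colnames(m),
                 inward = sh_in, outward = sh_out,
                 total_in = tot_in, total_out = tot_out,
                 mask_in = mask_in, mask_out = mask_out),
            class = "current_shares")
}

#' Mean current shares over a window
#'
#' Time-averaged inward and outward shares over a window, e.g. the 20 ms
#' following a burst end, to track how the burst-termination mechanism shifts
#' with temperature.
#'
#' @param shares A [current_shares()].
#' @param window Numeric `c(t0, t1)` in ms (trace time base); `NULL` averages
#'   the whole trace.
#' @return List of named mean-share vectors `inward` and `outward`, each
#'   summing to 100 when its class carries current in the window.
#' @export
share_summary <- function(shares, window = NULL) {
  idx <- if (is.null(window)) seq_along(shares$time)
  else which(shares$time >= window[1] & shares$time <= window[2])
  if (!length(idx)) stop("window outside the trace")
  avg <- function(sh, mask) {
    ok <- idx[mask[idx]]
    if (!length(ok)) return(setNames(rep(0, ncol(sh)), colnames(sh)))
    colMeans(sh[ok, , drop = FALSE])
  }
  list(inward = avg(shares$inward, shares$mask_in),
       outward = avg(shares$outward, shares$mask_out))
}

#' Burst-termination shares across temperature
#'
#' For each temperature, simulates the model, finds the bursts of one cell,
#' and averages the current shares in the window following each burst end
#' (20 ms by default).
#'
#' @param model A [pyloric_model()].
#' @param temperatures Temperature grid (degC).
#' @param cell Cell to analyze.
#' @param window_ms Window length after each burst end (ms).
#' @param duration,discard,dt Simulation protocol.
#' @param fast Use tabulated kinetics.
#' @return List with matrices `inward` and `outward` (temperature x current,
#'   mean shares in %), rows `NA` where the cell does not burst.
#' @export
termination_shares_sweep <- function(model, temperatures = seq(10, 25, 3),
                                     cell = "PD", window_ms = 20,
                                     duration = 20, discard = 10, dt = 0.05,
                                     fast = FALSE) {
  first <- TRUE
  inw <- outw <- NULL
  for (i in seq_along(temperatures)) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = temperatures[i], record = "full",
                   fast = fast)
    sh <- current_shares(tr, cell)
    if (first) {
      inw <- outw <- matrix(NA_real_, length(temperatures),
                            length(sh$currents),
                            dimnames = list(NULL, sh$currents))
      first <- FALSE
    }
    if (!is.na(tr$blow_time)) next
    bs <- burst_summary(tr)
    ends <- bs[[cell]]$bursts$end
    if (!length(ends)) next
    acc_in <- acc_out <- 0
    n_acc <- 0
    for (e in ends) {
      if (e + window_ms > max(tr$time)) next
      s <- share_summary(sh, c(e, e + window_ms))
      acc_in <- acc_in + s$inward
      acc_out <- acc_out + s$outward
      n_acc <- n_acc + 1
    }
    if (n_acc > 0) {
      inw[i, ] <- acc_in / n_acc
      outw[i, ] <- acc_out / n_acc
    }
  }
  list(temperatures = temperatures, inward = inw, outward = outw)
}

#' @export
plot.current_shares <- function(x, side = c("inward", "outward"),
                                col = NULL, ...) {
  side <- match.arg(side)
  sh <- x[[side]]
  n <- ncol(sh)
  if (is.null(col)) col <- grDevices::hcl.colors(n, "Spectral")
  cum <- t(apply(sh, 1, cumsum))
  graphics::plot(range(x$time), c(0, 100), type = "n", xlab = "time (ms)",
                 ylab = paste(side, "share (%)"), ...)
  for (k in n:1) {
    graphics::polygon(c(x$time, rev(x$time)),
                      c(cum[, k], rep(0, length(x$time))),
                      col = col[k], border = NA)
  }
  graphics::legend("topright", legend = x$currents, fill = col, cex = 0.6,
                   bg = "white")
  invisible(x)
}
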