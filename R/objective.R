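# Landscape-optimization error terms and composite objectives.

#' Sentinel penalty for failed candidates
#'
#' Discarded, quiescent, or blown-up candidates receive a large finite score
#' (plus the count of missing features, or the capped raw error for unstable
#' rhythms), so the search can still rank failures. Always strictly larger
#' than any validly scored objective.
#' @keywords internal
.SENTINEL <- 1e6

#' Target rhythm specification
#'
#' The control target is a 1 Hz triphasic rhythm with PD duty cycle 0.2, LP
#' and PY duty cycles 0.25, phase lags 0.5 (PD-LP) and 0.75 (PD-PY) in units
#' of the PD period, one slow-wave crossing per burst, and weights
#' (alpha, beta, gamma, eta) = (10, 1000, 1, 10) on the frequency,
#' duty-cycle, slow-wave, and phase error terms.
#'
#' @param f_tg Target burst frequency (Hz), all cells.
#' @param dc_tg Named target duty cycles per cell.
#' @param lag_tg Named target phase lags (fractions of the PD period).
#' @param weights Named weights `alpha`, `beta`, `gamma`, `eta`.
#' @param t_sw Slow-wave threshold (mV).
#' @return A `target_spec` list.
#' @export
target_spec <- function(f_tg = 1,
                        dc_tg = c(PD = 0.2, LP = 0.25, PY = 0.25),
                        lag_tg = c(PD.LP = 0.5, PD.PY = 0.75),
                        weights = c(alpha = 10, beta = 1000, gamma = 1,
                                    eta = 10),
                        t_sw = -50) {
  structure(list(f_tg = f_tg, dc_tg = dc_tg, lag_tg = lag_tg,
                 weights = weights, t_sw = t_sw),
            class = "target_spec")
}

#' Error terms of the landscape objective
#'
#' Ef sums the squared mismatch of each cell's mean burst frequency with the
#' target; Edc likewise for duty cycles; Esw penalizes the squared difference
#' between slow-wave crossing and burst counts (the rhythm should cross the
#' -50 mV slow-wave threshold exactly once per burst); Eph compares the mean
#' PD-LP and PD-PY lags (fractions of the PD period) to their targets.
#'
#' @param summary A [burst_summary()].
#' @param targets A [target_spec()].
#' @return Named numeric `c(Ef, Edc, Esw, Eph)`, all >= 0, or `NA`s when a
#'   required metric is undefined.
#' @export
error_components <- function(summary, targets = target_spec()) {
  ef <- edc <- esw <- 0
  for (cl in .cells) {
    b <- summary[[cl]]
    if (!length(b$fb) || !length(b$dc))
      return(c(Ef = NA_real_, Edc = NA_real_, Esw = NA_real_,
               Eph = NA_real_))
    ef <- ef + (targets$f_tg - mean(b$fb))^2
    edc <- edc + (targets$dc_tg[[cl]] - mean(b$dc))^2
    esw <- esw + (b$n_sw - b$n_bursts)^2
  }
  lags <- summary$lags
  if (any(is.na(lags)))
    return(c(Ef = ef, Edc = edc, Esw = esw, Eph = NA_real_))
  eph <- (targets$lag_tg[["PD.LP"]] - lags[["PD.LP"]])^2 +
         (targets$lag_tg[["PD.PY"]] - lags[["PD.PY"]])^2
  c(Ef = ef, Edc = edc, Esw = esw, Eph = eph)
}

# score a burst summary (weighted sum or sentinel); internal workhorse.
# Failed candidates score strictly above every validly scored one, but are
# still ranked so the search has a gradient through the failure regimes:
# blow-ups worst, then candidates with missing features (sentinel + a
# per-cell missing count, graded continuously by spike, burst, and
# slow-wave counts — quiescence is further from bursting than tonic
# spiking is), then defined-but-unstable rhythms (half-sentinel + their
# raw weighted error, capped below the sentinel).
.score_summary <- function(summary, targets) {
  cell_missing <- function(b) {
    if (length(b$fb) > 0 && length(b$dc) > 0) return(0)
    2 - 0.6 * min(length(b$spikes), 20) / 20 -
      0.4 * (b$n_bursts >= 1) -
      0.25 * min(b$n_sw, 4) / 4
  }
  missing <- sum(vapply(.cells, function(cl) cell_missing(summary[[cl]]),
                        numeric(1))) + any(is.na(summary$lags))
  if (missing > 0) return(.SENTINEL + missing)
  e <- error_components(summary, targets)
  w <- targets$weights
  score <- unname(w[["alpha"]] * e[["Ef"]] + w[["beta"]] * e[["Edc"]] +
                  w[["gamma"]] * e[["Esw"]] + w[["eta"]] * e[["Eph"]])
  unstable <- !all(vapply(.cells, function(cl) summary[[cl]]$stable,
                          logical(1)))
  if (unstable) return(.SENTINEL / 2 + min(score, .SENTINEL / 2 - 1))
  score
}

#' Control objective at one temperature
#'
#' E(G) = alpha Ef + beta Edc + gamma Esw + eta Eph, evaluated from a 20 s
#' simulation whose first 10 s are discarded. Candidates that blow up, fall
#' silent, or fail the stability filter receive the sentinel penalty.
#'
#' @param model A [pyloric_model()].
#' @param targets A [target_spec()].
#' @param temperature Evaluation temperature (degC).
#' @param duration,discard,dt Simulation protocol (s, s, ms).
#' @param stride Record stride for the analysis (the integration step is
#'   unaffected).
#' @param fast Use tabulated kinetics (optimization workloads).
#' @return List with `score`, the error `components`, and the `summary`
#'   (`NULL` on blow-up).
#' @export
control_objective <- function(model, targets = target_spec(),
                              temperature = 10, duration = 20, discard = 10,
                              dt = 0.05, stride = 1, fast = FALSE) {
  tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                 temperature = temperature, stride = stride, fast = fast)
  if (!is.na(tr$blow_time) || length(tr$time) == 0)
    return(list(score = .SENTINEL + 8, components = NULL, summary = NULL))
  bs <- burst_summary(tr, sw_threshold = targets$t_sw)
  list(score = .score_summary(bs, targets),
       components = error_components(bs, targets), summary = bs)
}

#' Temperature-robustness objective
#'
#' EC(Q10) = E(15 degC) + E(20 degC) + E(25 degC) + Ecrash(35 degC), where
#' Ecrash is the total spike count of the three cells at 35 degC over the
#' analysis window — robust networks keep the target rhythm over the working
#' range and fall silent near 35 degC.
#'
#' @param model A [pyloric_model()] (conductances from the control search,
#'   Q10 set under evaluation).
#' @param targets A [target_spec()].
#' @param control_temps Temperatures at which the full objective is scored.
#' @param crash_temp Temperature of the spike-count term.
#' @param duration,discard,dt Simulation protocol per temperature.
#' @param stride Record stride for the analysis.
#' @param fast Use tabulated kinetics.
#' @return List with `score`, per-temperature scores `by_temp`, and
#'   `e_crash`.
#' @export
thermal_objective <- function(model, targets = target_spec(),
                              control_temps = c(15, 20, 25), crash_temp = 35,
                              duration = 20, discard = 10, dt = 0.05,
                              stride = 1, fast = FALSE) {
  by_temp <- vapply(control_temps, function(T) {
    control_objective(model, targets, temperature = T, duration = duration,
                      discard = discard, dt = dt, stride = stride,
                      fast = fast)$score
  }, numeric(1))
  names(by_temp) <- paste0("T", control_temps)
  tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                 temperature = crash_temp, stride = stride, fast = fast)
  e_crash <- if (!is.na(tr$blow_time) || length(tr$time) == 0) .SENTINEL
  else sum(vapply(.cells, function(cl)
    length(detect_spikes(tr$V[, cl], tr$time)), numeric(1)))
  list(score = sum(by_temp) + e_crash, by_temp = by_temp, e_crash = e_crash)
}

#' Screen intermediate temperatures
#'
#' Scoring at a handful of control temperatures does not guarantee the rhythm
#' in between: the candidate is simulated on a grid (16 temperatures in
#' [10, 25] degC by default) and passes only if the network is classified
#' triphasic at every one.
#'
#' @param model A [pyloric_model()].
#' @param temperatures Screening grid (degC).
#' @param duration,discard,dt Per-temperature protocol.
#' @param fast Use tabulated kinetics.
#' @return List with `pass` and a data frame `by_temp` of network labels.
#' @export
screen_intermediate_temperatures <- function(model,
                                             temperatures = seq(10, 25,
                                                                length.out = 16),
                                             duration = 20, discard = 10,
                                             dt = 0.05, fast = FALSE) {
  labels <- vapply(temperatures, function(T) {
    tr <- simulate(model, duration = duration, discard = discard, dt = dt,
                   temperature = T, fast = fast)
    if (!is.na(tr$blow_time)) "not triphasic" else classify_network(tr)
  }, character(1))
  list(pass = all(labels == "triphasic"),
       by_temp = data.frame(temperature = temperatures, network = labels))
}
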