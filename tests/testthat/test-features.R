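# Feature extraction: spikes, bursts, duty cycles, phases, slow waves,
# stability rules.

test_that("spike detection on constructed traces", {
  time <- seq(0, 1000, by = 1)
  # flat trace: no spikes
  expect_length(detect_spikes(rep(-51, length(time)), time), 0)
  # ten sharp depolarizations above 0 mV
  v <- rep(-60, length(time))
  at <- seq(50, 950, by = 100)
  v[at + 1] <- 5
  expect_equal(detect_spikes(v, time), at)
  # refractory deduplication: double-sampled peaks count once
  v2 <- rep(-60, length(time))
  v2[c(101, 102)] <- 5   # 1 ms apart
  v2[c(201, 204)] <- 5   # 3 ms apart
  expect_equal(detect_spikes(v2, time), c(100, 200, 203))
})

test_that("burst grouping splits on gaps of at least 200 ms", {
  b <- group_bursts(c(0, 50, 100, 400, 450))
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(0, 400))
  expect_equal(b$end, c(100, 450))
  expect_equal(b$n_spikes, c(3L, 2L))
  expect_equal(nrow(group_bursts(numeric(0))), 0)
  expect_equal(nrow(group_bursts(seq(0, 1900, by = 100))), 1)
  # idempotent under chunk boundaries: grouping does not depend on how the
  # spike list was assembled
  sp <- c(0, 150, 300, 700, 850)
  expect_equal(group_bursts(sp), group_bursts(c(sp[1:3], sp[4:5])))
})

test_that("burst metrics on a perfectly periodic surrogate", {
  starts <- seq(0, 11000, by = 1000)
  b <- data.frame(start = starts, end = starts + 200,
                  n_spikes = rep(9L, length(starts)))
  m <- burst_metrics(b)
  expect_equal(m$fb, rep(1, length(starts) - 1))
  expect_equal(m$dc, rep(0.2, length(starts) - 1))
  expect_equal(m$period, 1000)
  # single burst: undefined metrics
  m1 <- burst_metrics(b[1, ])
  expect_length(m1$fb, 0)
  # one-spike bursts have zero duration hence zero duty cycle
  b0 <- data.frame(start = c(0, 1000), end = c(0, 1000), n_spikes = 1L)
  expect_equal(burst_metrics(b0)$dc, 0)
})

test_that("phase lags from construction, with translation invariance", {
  mk <- function(off, n = 10)
    data.frame(start = off + (0:(n - 1)) * 1000,
               end = off + (0:(n - 1)) * 1000 + 150, n_spikes = 5L)
  lag <- phase_lags(mk(0), mk(500), mk(750))
  expect_equal(unname(lag), c(0.5, 0.75))
  # LP coincident with PD
  expect_equal(unname(phase_lags(mk(0), mk(0), mk(250))[1]), 0)
  # global time shift leaves the lags unchanged
  shift <- 333.25
  lag2 <- phase_lags(mk(shift), mk(500 + shift), mk(750 + shift))
  expect_equal(lag2, lag)
  # a cell with no bursts propagates NA
  expect_true(all(is.na(phase_lags(mk(0), mk(500)[0, ], mk(750)))))
})

test_that("slow-wave crossings count burst envelopes, not spikes", {
  time <- seq(0, 10000, by = 1)
  # constant below threshold
  expect_equal(slow_wave_crossings(rep(-60, length(time)), time), 0)
  # clean envelope rising through -50 once per period over 10 periods
  v <- ifelse(time %% 1000 >= 200 & time %% 1000 < 500 & time < 10000,
              -40, -60)
  expect_equal(slow_wave_crossings(v, time), 10)
  # sub-threshold oscillation peaking at -55
  v2 <- -60 + 5 * (sin(2 * pi * time / 1000) > 0)
  expect_equal(slow_wave_crossings(v2, time), 0)
  # fast spikes alone are averaged away by the 50 ms smoothing
  v3 <- rep(-60, length(time))
  v3[seq(100, 9900, by = 1000)] <- 20
  expect_equal(slow_wave_crossings(v3, time), 0)
})

test_that("stability filter reproduces the printed discard rules", {
  # perfectly periodic: keep
  expect_true(stability_filter(rep(1, 10), rep(0.2, 9)))
  # fb alternating 0.5/1.5 Hz: sd = 0.5 >= 0.1 * mean -> discard
  expect_false(stability_filter(rep(c(0.5, 1.5), 5), rep(0.2, 9)))
  # small fb spread, constant dc: keep
  fb <- 1 + 0.05 * rep(c(-1, 1), 5)  # population sd = 0.05 < 0.1
  expect_true(stability_filter(fb, rep(0.2, 9)))
  # dc spread at the boundary: sd = 0.2 * mean -> discard
  dc <- 0.2 + 0.04 * rep(c(-1, 1), 5)
  expect_false(stability_filter(rep(1, 10), dc))
  # undefined metrics -> discard
  expect_false(stability_filter(numeric(0), numeric(0)))
  expect_false(stability_filter(1, 0.2))
})

test_that("ISI series and coefficient of variation", {
  expect_equal(isi_series(seq(0, 1000, by = 100))$cv, 0)
  # alternating 100/300 ms intervals: population CV exactly 0.5
  sp <- cumsum(c(0, rep(c(100, 300), 10)))
  expect_equal(isi_series(sp)$cv, 0.5)
  expect_length(isi_series(c(5))$isi, 0)
  expect_true(is.na(isi_series(c(5, 10))$cv))  # single ISI
})

test_that("burst summary recovers constructed rhythm statistics exactly", {
  sg <- make_surrogate_trains()
  bs <- burst_summary(sg$trace)
  expect_equal(bs$PD$mean_fb, 1)
  expect_equal(bs$PD$mean_dc, 0.2)
  expect_equal(bs$LP$mean_dc, 0.25)
  expect_equal(bs$PY$mean_dc, 0.25)
  expect_equal(unname(bs$lags), c(0.5, 0.75))
  for (cl in c("PD", "LP", "PY")) {
    expect_equal(bs[[cl]]$n_bursts, 12)
    expect_equal(bs[[cl]]$n_sw, 12)
    expect_true(bs[[cl]]$stable)
  }
})

test_that("duty cycle and phases are invariant under uniform time
          rescaling", {
  sg <- make_surrogate_trains(n_bursts = 8)
  tr <- sg$trace
  half_speed <- tr
  half_speed$time <- tr$time * 2
  bs <- burst_summary(tr)
  bs2 <- burst_summary(half_speed, gap = 400, sw_smooth = 100)
  expect_equal(bs2$PD$mean_dc, bs$PD$mean_dc)
  expect_equal(bs2$lags, bs$lags)
  expect_equal(bs2$PD$mean_fb, bs$PD$mean_fb / 2)
})

test_that("spike counts are stable under time-grid refinement", {
  m <- burster_model()
  a <- simulate(m, duration = 12, discard = 2, dt = 0.05)
  b <- simulate(m, duration = 12, discard = 2, dt = 0.025)
  na <- length(detect_spikes(a$V[, "PD"], a$time))
  nb <- length(detect_spikes(b$V[, "PD"], b$time))
  expect_equal(na, nb)
})

test_that("voltage distributions are normalized per temperature", {
  lk <- make_leak_cell(gleak = 0.1)
  vd <- voltage_distribution_sweep(lk$model, cell = "PD",
                                   temperatures = c(10, 20),
                                   duration = 0.5, discard = 0.25,
                                   dt = 0.05, n_samples = 1000)
  expect_equal(rowSums(vd$density), c(1, 1), tolerance = 1e-9)
  # quiescent cell resting at Eleak: all mass in one bin
  expect_equal(apply(vd$density, 1, max), c(1, 1))
})
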