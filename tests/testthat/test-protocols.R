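# Temperature sweeps, hysteresis ramps, acute deletions, crash finding.

test_that("ramp presets are piecewise linear and time-symmetric", {
  r <- ramp_up_down(10, 35, 30)
  expect_equal(nrow(r), 3)
  expect_equal(r[, 2], c(10, 35, 10))
  expect_equal(diff(r[, 1]), rep(30 * 60 * 1000, 2))
  r2 <- ramp_up_down(10, 25, 60, down = FALSE)
  expect_equal(nrow(r2), 2)
  expect_equal(r2[2, 1], 60 * 60 * 1000)
})

test_that("a single-temperature sweep reduces to one simulate call", {
  m <- burster_model()
  sw <- temperature_sweep(m, temperatures = 10, duration = 12, discard = 2)
  expect_equal(nrow(sw), 1)
  tr <- simulate(m, duration = 12, discard = 2, temperature = 10)
  bs <- burst_summary(tr)
  expect_equal(sw$fb.PD, bs$PD$mean_fb)
  expect_equal(sw$dc.PD, bs$PD$mean_dc)
  expect_false(sw$failed)
})

test_that("sweeps record failures and continue", {
  lk <- make_leak_cell()
  sw <- temperature_sweep(lk$model, temperatures = c(10, 20),
                          duration = 2, discard = 1)
  expect_equal(nrow(sw), 2)
  expect_true(all(is.na(sw$fb.PD)))
  expect_true(all(sw$network == "not triphasic"))
})

test_that("hysteresis report is not applicable for a never-quiet or
          never-spiking cell", {
  # leak cell never spikes: no cessation, flag unset
  lk <- make_leak_cell()
  rep1 <- ramp_with_hysteresis(lk$model,
                               ramp = ramp_up_down(10, 35, 0.05),
                               stride = 4)
  expect_false(rep1$applicable)
  expect_false(rep1$multistable)
  expect_true(is.na(rep1$cessation))
})

test_that("acute deletion: fraction 1 leaves the rhythm unchanged, and the
          perturbation only acts after the switch", {
  m <- burster_model()
  del <- acute_deletion(m, "gNa", fraction = 1, temperature = 10,
                        segment = 8)
  expect_false(is.null(del$pre))
  # statistically identical continuation: same burst frequency within the
  # stability-filter tolerance
  expect_equal(del$post$PD$mean_fb, del$pre$PD$mean_fb, tolerance = 0.1)
  # complete Na removal abolishes spiking in the post segment only
  del0 <- acute_deletion(m, "gNa", fraction = 0, temperature = 10,
                         segment = 8)
  expect_gt(length(del0$pre$PD$spikes), 5)
  # fast Na spikes disappear; any residual crossings are slow Ca events
  expect_lt(length(del0$post$PD$spikes),
            length(del0$pre$PD$spikes) / 2)
})

test_that("deleting the leak from a leak-only cell freezes the membrane", {
  lk <- make_leak_cell(gleak = 0.1)
  del <- acute_deletion(lk$model, "gleak", fraction = 0, temperature = 10,
                        segment = 1)
  v <- del$trace$V[, "PD"]
  t <- del$trace$time
  post <- v[t > del$t_switch]
  # with no currents left, V holds its value at the switch
  expect_lt(max(abs(post - post[1])), 1e-9)
  # before the switch it relaxed toward Eleak
  expect_equal(v[t <= del$t_switch][sum(t <= del$t_switch)], -50,
               tolerance = 1e-3)
})

test_that("crash finder reports censored when no crash exists in range", {
  sg_period <- 1000
  # a quiescent model is 'not triphasic' at the range start: warning path
  lk <- make_leak_cell()
  expect_warning(res <- crash_finder(lk$model, t_range = c(25, 27),
                                     step = 1, duration = 2, discard = 1),
                 "not triphasic")
  expect_false(res$censored)
  expect_equal(res$crash_temp, 25)
})

test_that("protocols are deterministic given model and config", {
  m <- burster_model()
  s1 <- temperature_sweep(m, temperatures = c(10, 14), duration = 6,
                          discard = 2)
  s2 <- temperature_sweep(m, temperatures = c(10, 14), duration = 6,
                          discard = 2)
  expect_identical(s1, s2)
})
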