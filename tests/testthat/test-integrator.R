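# RK4 integration: initial conditions, analytic oracles, convergence order,
# determinism.

test_that("canonical initial state", {
  st <- initial_state()
  expect_length(st, 46)
  expect_equal(unname(st[grep("\\.V$", names(st))]), rep(-51, 3))
  expect_equal(unname(st[grep("\\.Ca$", names(st))]), rep(5, 3))
  gates <- st[!grepl("\\.(V|Ca)$", names(st))]
  expect_equal(unname(gates), rep(0, 40))  # 11 gates x 3 cells + 7 synapses
})

test_that("network derivative: length, determinism, fixed points", {
  m <- burster_model()
  st <- initial_state()
  d1 <- network_derivatives(st, m)
  expect_length(d1, 46)
  expect_identical(d1, network_derivatives(st, m))  # bit-identical
  # leak-only cell at its reversal potential is at equilibrium
  lk <- make_leak_cell()
  st2 <- st
  st2[grep("\\.V$", names(st))] <- -50
  d <- network_derivatives(st2, lk$model)
  expect_equal(d[[1]], 0)
  expect_error(network_derivatives(replace(st, 1, NaN), m), "finite")
})

test_that("rk4 step: zero derivative leaves state unchanged; leak step
          matches the exponential to O(dt^5)", {
  lk <- make_leak_cell()
  st <- initial_state()
  st[grep("\\.V$", names(st))] <- -50
  st[grep("\\.Ca$", names(st))] <- pyloric_constants()$ca_rest
  # gating variables relax, but V and Ca of the leak cell stay put
  out <- rk4_step(st, lk$model)
  expect_equal(out[["PD.V"]], -50)
  # single-step local error against the closed form
  st0 <- initial_state()
  dt <- 0.05
  out1 <- rk4_step(st0, lk$model, dt = dt)
  expect_equal(out1[["PD.V"]], lk$voltage(dt), tolerance = 1e-12)
})

test_that("RK4 convergence order on the leak cell is at least 3.5", {
  lk <- make_leak_cell(gleak = 0.1)  # tau = 6.28 ms, fast enough to resolve
  errs <- vapply(c(2, 1, 0.5), function(dt) {
    tr <- simulate(lk$model, duration = 0.05, discard = 0, dt = dt)
    max(abs(tr$V[, "PD"] - lk$voltage(tr$time)))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("simulate: protocol windows, determinism, quiescent sanity", {
  m <- burster_model()
  # 20 s run with 10 s discard returns exactly the final 10 s
  tr <- simulate(m, duration = 2, discard = 1, dt = 0.05)
  expect_equal(min(tr$time), 1000)
  expect_equal(max(tr$time), 2000)
  expect_equal(length(tr$time), 20001)
  # zero-length record window: empty trace, no error
  tr0 <- simulate(m, duration = 1, discard = 1)
  expect_equal(length(tr0$time), 1)  # single boundary sample
  # determinism
  t1 <- simulate(m, duration = 1.5, discard = 0.5)
  t2 <- simulate(m, duration = 1.5, discard = 0.5)
  expect_identical(t1$V, t2$V)
  # with every conductance removed the membrane holds its potential
  empty <- pyloric_model(channel_set(), channel_set(), channel_set(),
                         gsyn = rep(0, 7))
  tre <- simulate(empty, duration = 1, discard = 0)
  expect_equal(unname(tre$V[, "PD"]), rep(-51, length(tre$time)))
})

test_that("halving dt barely changes a bursting trajectory", {
  m <- burster_model()
  a <- simulate(m, duration = 1.5, discard = 0, dt = 0.05)
  b <- simulate(m, duration = 1.5, discard = 0, dt = 0.025, stride = 2)
  expect_equal(length(a$time), length(b$time))
  # sub-threshold approach to the first burst: pointwise convergence
  pre <- a$time <= 500
  expect_lt(max(abs(a$V[pre, "PD"] - b$V[pre, "PD"])), 1e-6)
  # across the burst, spike times (not pointwise V on the steep upstrokes)
  # are the stable observable: every spike shifts by well under 1 ms
  sa <- detect_spikes(a$V[, "PD"], a$time)
  sb <- detect_spikes(b$V[, "PD"], b$time)
  expect_equal(length(sa), length(sb))
  expect_lt(max(abs(sa - sb)), 1)
})

test_that("gating variables and synaptic activations stay in [0, 1] along
          trajectories", {
  m <- burster_model()
  st <- initial_state()
  for (i in 1:400) st <- rk4_step(st, m, temperature = 25, dt = 0.1)
  gates <- st[!grepl("\\.(V|Ca)$", names(st))]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("temperature schedules are evaluated per step", {
  m <- make_leak_cell()$model
  ramp <- matrix(c(0, 1000, 10, 30), ncol = 2)
  tr <- simulate(m, duration = 1, discard = 0, temperature = ramp)
  expect_equal(tr$temperature[1], 10)
  expect_equal(tr$temperature[length(tr$temperature)], 30)
  expect_true(all(diff(tr$temperature) > 0))
})

test_that("trace files round-trip the series and the model header", {
  m <- burster_model()
  tr <- simulate(m, duration = 0.4, discard = 0.2, stride = 4,
                 record = "full")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$V, tr$V, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr2$currents, tr$currents, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(coef(tr2$model), coef(m), tolerance = 1e-12)
  cfg <- attr(tr2, "config")
  expect_equal(cfg$dt, 0.05)
  expect_equal(cfg$stride, 4)
  # the header is sufficient to replay the simulation exactly
  tr3 <- simulate(tr2$model, duration = cfg$duration,
                  discard = cfg$discard, dt = cfg$dt, stride = cfg$stride,
                  record = cfg$record)
  expect_identical(tr3$V, tr$V)
})
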