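# Channel gating, Nernst reversal, and synapse kinetics.

test_that("gating steady states are bounded and time constants positive", {
  cst <- pyloric_constants()
  vs <- seq(-120, 80, by = 2.5)
  for (g in cst$gates) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    out <- gating_steady_state(parts[1], parts[2], vs, ca = 2)
    expect_true(all(out$inf >= 0 & out$inf <= 1), info = g)
    expect_true(all(out$tau > 0), info = g)
  }
  expect_error(gating_steady_state("Kd", "h", 0), "unknown")
})

test_that("gating limits: KCa vanishes at zero calcium, Na m saturates", {
  kca <- gating_steady_state("KCa", "m", v = 0, ca = 1e-9)
  expect_lt(kca$inf, 1e-9)
  # the calcium factor is Ca/(Ca+3): half-activation at 3 uM
  expect_equal(gating_steady_state("KCa", "m", v = 60, ca = 3)$inf,
               gating_steady_state("KCa", "m", v = 60, ca = 1e9)$inf / 2,
               tolerance = 1e-6)
  expect_gt(gating_steady_state("Na", "m", v = 120)$inf, 1 - 1e-8)
  expect_lt(gating_steady_state("Na", "h", v = 120)$inf, 1e-8)
})

test_that("intrinsic currents follow the ohmic form", {
  # zero conductance gives zero current regardless of state
  expect_equal(intrinsic_current("Na", v = 30, m = 1, h = 1, g = 0), 0)
  # zero driving force gives zero current
  expect_equal(intrinsic_current("Kd", v = -80, m = 0.7, g = 1), 0)
  # leak: I = g (V - E) -> 0.01 uS * (-51 + 50) mV = -0.01 nA
  expect_equal(intrinsic_current("leak", v = -51, g = 0.01), -0.01)
  # gating exponents: Kd uses m^4
  expect_equal(intrinsic_current("Kd", v = -60, m = 0.5, g = 1),
               0.5^4 * (-60 + 80))
  # calcium currents demand an explicit reversal
  expect_error(intrinsic_current("CaS", v = -40, m = 0.2, h = 0.5, g = 1),
               "eca")
  expect_equal(intrinsic_current("CaS", v = 120, m = 1, h = 1, g = 2,
                                 eca = 120), 0)
})

test_that("Nernst calcium reversal identities", {
  # equal concentrations: zero potential
  expect_equal(nernst_eca(3000, 10, ca_out = 3000), 0)
  # halving internal calcium raises ECa by (R T ln 2)/(2F)
  inc <- nernst_eca(2.5, 10) - nernst_eca(5, 10)
  inc_expected <- 1000 * 8.314462618 * 283.15 / (2 * 96485.33212) * log(2)
  expect_equal(inc, inc_expected, tolerance = 1e-12)
  expect_equal(inc, 8.46, tolerance = 0.01)
  # strictly increasing in temperature when ca_out > ca_in
  temps <- seq(5, 35, by = 5)
  ecas <- vapply(temps, function(T) nernst_eca(5, T), numeric(1))
  expect_true(all(diff(ecas) > 0))
  expect_error(nernst_eca(0), "positive")
})

test_that("synaptic activation sigmoid and derivative", {
  # midpoint at Vth = -35 mV
  expect_equal(synapse_steady_state(-35), 0.5)
  expect_equal(synapse_steady_state(-30), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_gt(synapse_steady_state(100), 1 - 1e-8)
  # monotone increasing
  vs <- seq(-80, 20, by = 1)
  expect_true(all(diff(synapse_steady_state(vs)) > 0))

  # fixed point: s at steady state has zero derivative
  sinf <- synapse_steady_state(-30)
  expect_equal(synapse_derivative(sinf, -30, "glut"), 0)
  # saturated presynaptic drive: timescale floored at tau_r = 20 ms
  expect_equal(synapse_derivative(0, 1000, "glut"), (1 - 0) / 20,
               tolerance = 1e-9)
  # hyperpolarized drive: tau_s = 1/k_minus (40 ms glut), total 60 ms
  expect_equal(synapse_derivative(0.6, -1000, "glut"), (0 - 0.6) / 60,
               tolerance = 1e-9)
  # cholinergic decay is slower: tau_s = 100 ms, total 120 ms
  expect_equal(synapse_derivative(0.6, -1000, "chol"), (0 - 0.6) / 120,
               tolerance = 1e-9)
  # a synaptic-timescale Q10 factor of 2 doubles the rate
  expect_equal(synapse_derivative(0.6, -1000, "glut", r_tau = 2),
               2 * synapse_derivative(0.6, -1000, "glut"))
})

test_that("synaptic current product form", {
  expect_equal(synaptic_current(0.5, -70, 0.01, "glut"), 0)
  expect_equal(synaptic_current(0, -20, 0.01, "glut"), 0)
  expect_equal(synaptic_current(0.5, -50, 0.01, "glut"), 0.1)
  # cholinergic reversal is -80 mV
  expect_equal(synaptic_current(1, -80, 0.02, "chol"), 0)
})
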