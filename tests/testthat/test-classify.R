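# Single-cell decision tree and network triphasic test.

# envelope-trace builder: spikes at given times riding an optional plateau
mk_trace <- function(spike_times, total = 20000, dt = 1, baseline = -60,
                     plateau_at = NULL, plateau_len = 0, plateau = -45) {
  time <- seq(0, total, by = dt)
  v <- rep(baseline, length(time))
  if (!is.null(plateau_at)) {
    for (s in plateau_at) v[time >= s & time <= s + plateau_len] <- plateau
  }
  v[round(spike_times / dt) + 1] <- 10
  list(v = v, time = time)
}

test_that("quiescent gate comes first: one spike or one ISI", {
  tr <- mk_trace(c(5000))
  expect_equal(classify_cell(tr$v, tr$time), "quiescent")
  tr2 <- mk_trace(c(5000, 6000))  # exactly one ISI
  expect_equal(classify_cell(tr2$v, tr2$time), "quiescent")
  tr0 <- mk_trace(numeric(0))
  expect_equal(classify_cell(tr0$v, tr0$time), "quiescent")
})

test_that("regular trains split into tonic vs single-spike bursting by the
          slow-wave lag", {
  # spikes every 500 ms, each on its own 100 ms slow wave starting 80 ms
  # before the spike: lag >= 20 ms -> single-spike bursting
  at <- seq(1000, 19000, by = 500)
  tr <- mk_trace(at, plateau_at = at - 80, plateau_len = 150)
  expect_equal(classify_cell(tr$v, tr$time), "single-spike bursting")
  # same train with the envelope rising just before each spike: tonic
  tr2 <- mk_trace(at, plateau_at = at - 5, plateau_len = 150)
  expect_equal(classify_cell(tr2$v, tr2$time), "tonic spiking")
  # regular train with no slow wave at all: tonic
  tr3 <- mk_trace(at)
  expect_equal(classify_cell(tr3$v, tr3$time), "tonic spiking")
})

test_that("bursting labels follow duty-cycle and frequency dispersion", {
  # periodic multi-spike bursts: regular bursting
  sg <- make_surrogate_trains()
  expect_equal(classify_cell(sg$trace, cell = "PD"), "regular bursting")
  # irregular burst durations (CV_dc > 1): irregular bursting
  set.seed(5)
  starts <- seq(500, 18500, by = 1000)
  sp <- unlist(lapply(starts, function(s) {
    len <- sample(c(0, 0, 0, 600), 1)  # mostly single spikes, a few long
    if (len == 0) s else seq(s, s + len, by = 30)
  }))
  tr <- mk_trace(sp)
  expect_equal(classify_cell(tr$v, tr$time), "irregular bursting")
  # all single-spike bursts at irregular times: irregular spiking
  set.seed(6)
  sp2 <- cumsum(runif(30, 250, 1500))
  tr2 <- mk_trace(sp2, total = ceiling(max(sp2) + 1000))
  expect_equal(classify_cell(tr2$v, tr2$time), "irregular spiking")
})

test_that("the decision tree is total on randomized surrogates", {
  labels <- c("regular bursting", "irregular bursting", "tonic spiking",
              "irregular spiking", "single-spike bursting", "quiescent",
              "other")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(0:60, 1)
    sp <- sort(runif(n, 0, 20000))
    sp <- sp[c(TRUE, diff(sp) > 3)]
    tr <- mk_trace(sp)
    lab <- classify_cell(tr$v, tr$time)
    expect_true(lab %in% labels, info = paste("case", i))
    expect_length(lab, 1)
  }
})

test_that("label is stable across disjoint windows of a regular surrogate", {
  sg <- make_surrogate_trains(n_bursts = 20)
  tr <- sg$trace
  w1 <- tr$time < 10000
  w2 <- tr$time >= 10000
  expect_equal(classify_cell(tr$V[w1, "PD"], tr$time[w1]),
               classify_cell(tr$V[w2, "PD"], tr$time[w2]))
})

test_that("triphasic networks need matched frequencies and PD-LP-PY order", {
  expect_equal(classify_network(make_surrogate_trains()$trace), "triphasic")
  # wrong order: PD -> PY -> LP
  wrong <- make_surrogate_trains(lags = c(PD.LP = 0.75, PD.PY = 0.5))
  expect_equal(classify_network(wrong$trace), "not triphasic")
  # one quiescent cell
  sg <- make_surrogate_trains()
  sg$trace$V[, "LP"] <- -60
  expect_equal(classify_network(sg$trace), "not triphasic")
  # frequency mismatch beyond 5%: bursts drift apart
  bs <- burst_summary(make_surrogate_trains()$trace)
  bs$PY$fb <- bs$PY$fb * 1.2
  bs$PY$mean_fb <- mean(bs$PY$fb)
  expect_equal(classify_network(bs), "not triphasic")
})

test_that("response grids have the 5 x 4 layout with control on top", {
  lk <- make_leak_cell()
  g <- response_grid(lk$model, "gleak", temperature = 10, duration = 2,
                     discard = 1)
  expect_equal(nrow(g), 5)
  expect_equal(colnames(g), c("level", "PD", "LP", "PY", "NET"))
  expect_equal(g$level, c(1, 0.75, 0.5, 0.25, 0))
  # a quiescent model stays quiescent at every removal level
  expect_true(all(g$PD == "quiescent"))
  expect_true(all(g$NET == "not triphasic"))
})

test_that("removal comparison covers the whole 0% row and is symmetric", {
  lk <- make_leak_cell()
  g1 <- response_grid(lk$model, "gleak", 10, duration = 2, discard = 1)
  g2 <- g1
  expect_equal(compare_removal_across_temperatures(g1, g2), "same")
  g2$NET[g2$level == 0] <- "triphasic"
  expect_equal(compare_removal_across_temperatures(g1, g2), "different")
  expect_equal(compare_removal_across_temperatures(g2, g1), "different")
  # a differing cell label alone makes the responses different
  g3 <- g1
  g3$LP[g3$level == 0] <- "tonic spiking"
  expect_equal(compare_removal_across_temperatures(g1, g3), "different")
  # non-0% rows are ignored
  g4 <- g1
  g4$PD[g4$level == 1] <- "other"
  expect_equal(compare_removal_across_temperatures(g1, g4), "same")
})
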