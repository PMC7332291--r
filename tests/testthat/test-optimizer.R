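# Genetic-algorithm machinery on analytic oracles.

test_that("search spaces encode the published bounds and grid", {
  sp <- search_space_conductances()
  expect_equal(nrow(sp), 34)
  expect_equal(sp$upper[sp$name == "PD.gNa"], 1000)
  expect_equal(sp$upper[sp$name == "LP.gKCa"], 1000)
  expect_equal(sp$upper[sp$name == "PY.gleak"], 10)
  expect_equal(sp$upper[sp$name == "PD.tauCa"], 2000)
  expect_true(all(sp$upper[grepl("^gsyn", sp$name)] == 0.05))
  expect_true(all(sp$levels == 1000))
  # tauCa floored one grid level above zero
  expect_true(all(sp$min_level[grepl("tauCa", sp$name)] == 1))
  v <- decode_levels(sp, sp$min_level)
  expect_gt(v[["PD.tauCa"]], 0)
  sq <- search_space_q10()
  expect_equal(nrow(sq), 24)
  expect_equal(max(decode_levels(sq, rep(999, 24))[1:8]), 2)  # conductance
  expect_equal(decode_levels(sq, rep(999, 24))[["q10.tau.Na.m"]], 4)
})

test_that("GA finds an exact grid point of a convex objective", {
  sp <- search_space(paste0("x", 1:20), lower = rep(0, 20),
                     upper = rep(1, 20), levels = 101)
  target <- decode_levels(sp, rep(37, 20))
  obj <- function(v) sum((v - target)^2)
  res <- ga_minimize(obj, sp, ga_config(population = 100, generations = 200,
                                        seed = 42, stop_score = 1e-12,
                                        patience = 3))
  expect_equal(res$best_score, 0)
  expect_true(all(res$best_levels == 37))
  expect_lte(max(res$log$generation), 200)
})

test_that("GA matches exhaustive search on a 3-parameter sub-grid", {
  sp <- search_space(c("a", "b", "c"), lower = c(0, -1, 2),
                     upper = c(1, 1, 4), levels = 11)
  # non-separable but unimodal on the grid
  obj <- function(v) (v[1] - 0.4)^2 + (v[2] * v[1] + 0.3)^2 + (v[3] - 3.1)^4
  grid <- expand.grid(a = 0:10, b = 0:10, c = 0:10)
  brute <- apply(grid, 1, function(lv) obj(decode_levels(sp, lv)))
  best_brute <- min(brute)
  res <- ga_minimize(obj, sp, ga_config(population = 60, generations = 120,
                                        seed = 7, stop_score = -1,
                                        patience = 5))
  expect_equal(res$best_score, best_brute, tolerance = 1e-12)
  expect_equal(unname(res$best_levels),
               unname(unlist(grid[which.min(brute), ])))
})

test_that("GA is reproducible, elitist, and grid-contained", {
  sp <- search_space(paste0("x", 1:5), lower = rep(0, 5), upper = rep(1, 5),
                     levels = 51)
  obj <- function(v) sum(abs(v - 0.3))
  cfg <- ga_config(population = 30, generations = 40, seed = 11,
                   stop_score = -1, patience = 5)
  r1 <- ga_minimize(obj, sp, cfg)
  r2 <- ga_minimize(obj, sp, cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$population, r2$population)
  # best-so-far is monotone non-increasing (elitism)
  expect_true(all(diff(r1$log$best) <= 0))
  # every candidate is exactly on the grid
  expect_true(all(r1$population == round(r1$population)))
  expect_true(all(r1$population >= 0 & r1$population <= 50))
  # objective failures become sentinel scores, never aborts
  obj_fail <- function(v) if (v[1] > 0.5) stop("boom") else sum(v)
  rf <- ga_minimize(obj_fail, sp,
                    ga_config(population = 10, generations = 5, seed = 3,
                              stop_score = -1, patience = 2))
  expect_true(is.finite(rf$best_score))
  expect_lt(rf$best_values[["x1"]], 0.5 + 1e-12)
})

test_that("seed is mandatory and population bounded", {
  expect_error(ga_config(population = 10), "seed")
  expect_error(ga_config(population = 1, seed = 1), "at least 2")
})
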