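test_that("simulation matches the logistic closed form without predation", {
  p <- carrgo_params(rho = 1.4, K = 5, kappa1 = 0, kappa2 = 1, theta = 0.3)
  tt <- seq(0, 6, by = 0.05)
  sim <- carrgo_simulate(p, x0 = 1.5, y0 = 0, times = tt, unit = "days")
  xan <- 5 * 1.5 * exp(1.4 * tt) / (5 + 1.5 * (exp(1.4 * tt) - 1))
  expect_lt(max(abs(sim$x_ci - xan) / xan), 1e-6)
  expect_equal(sim$y_ci, rep(0, length(tt)))
})

test_that("predator-only dynamics match the separable closed form", {
  # x = 0: dy/dt = -(theta + c3 e^{-sigma t}) y integrates in closed form
  p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 1, theta = 0.6,
                     c3 = -2.4, sigma = 5, D0 = 0.1)
  tt <- seq(0, 3, by = 0.02)
  sim <- carrgo_simulate(p, x0 = 0, y0 = 0.5, times = tt, unit = "days")
  yan <- 0.5 * exp(-0.6 * tt + (-2.4 / 5) * (exp(-5 * tt) - 1))
  expect_lt(max(abs(sim$y_ci - yan) / yan), 1e-6)
  expect_equal(sim$x_ci, rep(0, length(tt)))
})

test_that("carrying-capacity start is a fixed point", {
  p <- carrgo_params(rho = 2, K = 3, kappa1 = 1, kappa2 = 1, theta = 0.5)
  sim <- carrgo_simulate(p, x0 = 3, y0 = 0, times = seq(0, 5, 0.25),
                         unit = "days")
  expect_equal(sim$x_ci, rep(3, nrow(sim)), tolerance = 1e-8)
})

test_that("integrated Dex matches the analytic exponential", {
  p <- carrgo_params(1, 5, 2, 1, 0.3, c0 = -0.5, c3 = 0.3, sigma = 5,
                     D0 = 0.5)
  tt <- seq(0, 2, by = 0.01)
  sim <- carrgo_simulate(p, 1.5, 0.4, times = tt, unit = "days",
                         system = "autonomous", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sim$dex_ugml - 0.5 * exp(-5 * tt)) /
                  (0.5 * exp(-5 * tt))), 1e-8)
})

test_that("the two formulations and the two engines agree", {
  p <- carrgo_params(1, 5, 2, 1, 0.6, c0 = -0.5, c3 = -2.4, sigma = 5,
                     D0 = 0.1)
  tt <- seq(0, 4, by = 0.05)
  s_non <- carrgo_simulate(p, 2, 0.5, tt, unit = "days")
  s_aut <- carrgo_simulate(p, 2, 0.5, tt, unit = "days",
                           system = "autonomous")
  s_r <- carrgo_simulate(p, 2, 0.5, tt, unit = "days", engine = "R")
  expect_equal(s_non$x_ci, s_aut$x_ci, tolerance = 1e-6)
  expect_equal(s_non$y_ci, s_aut$y_ci, tolerance = 1e-6)
  expect_equal(s_non$x_ci, s_r$x_ci, tolerance = 1e-8)
})

test_that("tightening tolerances changes the solution by less than the coarser tolerance", {
  p <- carrgo_params(1, 5, 2, 1, 0.25, c0 = -0.5, c3 = 0.3, sigma = 5,
                     D0 = 0.01)
  tt <- seq(0, 6, by = 0.05)
  coarse <- carrgo_simulate(p, 2, 0.5, tt, unit = "days",
                            rtol = 1e-6, atol = 1e-8)
  fine <- carrgo_simulate(p, 2, 0.5, tt, unit = "days",
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(coarse$x_ci - fine$x_ci) / pmax(fine$x_ci, 1e-3)), 1e-5)
})

test_that("trajectories stay non-negative from non-negative starts", {
  set.seed(5)
  for (p in rand_params(10, with_dex = TRUE)) {
    sim <- carrgo_simulate(p, x0 = runif(1, 0, 5), y0 = runif(1, 0, 3),
                           times = seq(0, 96, by = 1))
    expect_true(all(is.finite(sim$x_ci)) && all(sim$x_ci >= 0))
    expect_true(all(is.finite(sim$y_ci)) && all(sim$y_ci >= 0))
  }
})

test_that("input validation rejects bad grids and states", {
  p <- carrgo_params(1, 5, 2, 1, 0.3)
  expect_error(carrgo_simulate(p, -1, 0, c(0, 1)), "non-negative")
  expect_error(carrgo_simulate(p, 1, 0, c(1, 1, 2)), "increasing")
})

test_that("outcome detection separates death from progression", {
  p <- carrgo_params(rho = 1, K = 5, kappa1 = 0, kappa2 = 1, theta = 0.3)
  grow <- carrgo_simulate(p, 1.5, 0, seq(0, 144, 1))
  expect_equal(detect_outcome(grow)$outcome, "tumor_progression")

  zero <- tibble::tibble(time_hr = 0:10, x_ci = 0)
  out0 <- detect_outcome(zero)
  expect_equal(out0$outcome, "tumor_death")
  expect_equal(out0$event_time_hr, 0)

  # a dip below threshold that recovers is not death
  dip <- tibble::tibble(time_hr = 0:4, x_ci = c(1, 0.005, 0.005, 0.5, 1))
  expect_equal(detect_outcome(dip)$outcome, "tumor_progression")

  bad <- tibble::tibble(time_hr = 0:1, x_ci = c(1, NaN))
  expect_error(detect_outcome(bad), "non-finite")
})

test_that("low Dex permits tumor eradication, high Dex prevents it", {
  # the success/failure regimes of the default condition map, E:T = 1:4
  lo <- default_truth("l", "1:4", 1e-3)
  hi <- default_truth("l", "1:4", 1e-1)
  tt <- seq(0, 144, by = 0.25)
  expect_equal(detect_outcome(carrgo_simulate(lo, 2, 0.5, tt))$outcome,
               "tumor_death")
  expect_equal(detect_outcome(carrgo_simulate(hi, 2, 0.5, tt))$outcome,
               "tumor_progression")
})

test_that("trajectory CSV export round-trips", {
  p <- carrgo_params(1, 5, 2, 1, 0.3)
  sim <- carrgo_simulate(p, 1.5, 0.4, seq(0, 24, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("time_hr", "x_ci", "y_ci", "dex_ugml"))
  expect_equal(back$x_ci, sim$x_ci)
})
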