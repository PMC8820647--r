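test_that("particle swarm solves standard test functions reproducibly", {
  r1 <- pso_search(function(x) (x - 3)^2, lower = 0, upper = 10, seed = 1,
                   n_particles = 20, iters = 50)
  expect_equal(r1$par, 3, tolerance = 1e-3)

  sphere <- function(x) sum(x^2)
  r5 <- pso_search(sphere, lower = rep(-5, 5), upper = rep(5, 5), seed = 2)
  expect_lt(r5$value, 1e-4)

  # same seed, same answer; non-finite objectives handled as penalties
  r1b <- pso_search(function(x) (x - 3)^2, lower = 0, upper = 10, seed = 1,
                    n_particles = 20, iters = 50)
  expect_identical(r1$par, r1b$par)
  rr <- pso_search(function(x) if (x[1] > 0.5) NaN else (x[1] - 0.2)^2,
                   lower = 0, upper = 1, seed = 3,
                   n_particles = 15, iters = 40)
  expect_equal(rr$par, 0.2, tolerance = 1e-2)
  expect_error(pso_search(function(x) x, lower = 0, upper = 1), "seed")
})

test_that("objective is zero at the generating truth and scales with weights", {
  gen <- small_staged_dataset(seed = 7)
  cond <- condition_data(gen$data, "SYN-GBM-1", "1:4", 1e-3)
  truth <- gen$truth$params[[which(gen$truth$et_ratio == "1:4" &
                                     gen$truth$dex0_ugml == 1e-3)]]
  f <- carrgo_objective(truth, cond)
  expect_lt(f, 1e-8)

  # away from truth the objective is positive; doubling weights doubles it
  p_off <- update_params(truth, theta = truth$theta * 1.5)
  ctrl1 <- fit_control()
  ctrl2 <- fit_control(w_x = 2, w_y = 2 * cond_weights_for_test(cond))
  f1 <- carrgo_objective(p_off, cond, ctrl1)
  f2 <- carrgo_objective(p_off, cond, ctrl2)
  expect_gt(f1, 1e-4)
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
})

test_that("each free parameter is locally identifiable at the truth", {
  gen <- small_staged_dataset(seed = 7)
  cond <- condition_data(gen$data, "SYN-GBM-1", "1:4", 1e-3)
  truth <- gen$truth$params[[which(gen$truth$et_ratio == "1:4" &
                                     gen$truth$dex0_ugml == 1e-3)]]
  f0 <- carrgo_objective(truth, cond)
  for (nm in c("rho", "K", "kappa1", "kappa2", "theta", "c0", "c3")) {
    for (fac in c(0.95, 1.05)) {
      val <- unclass(truth)[[nm]]
      val_p <- if (val == 0) 0.05 * (fac - 1) / 0.05 else val * fac
      p <- do.call(update_params, setNames(list(truth, val_p),
                                           c("params", nm)))
      expect_gt(carrgo_objective(p, cond), f0 + 1e-6)
    }
  }
})

test_that("LM refinement stays at the truth and never degrades the start", {
  gen <- small_staged_dataset(seed = 7)
  cond <- condition_data(gen$data, "SYN-GBM-1", NA, 0)
  truth <- gen$truth$params[[which(is.na(gen$truth$et_ratio) &
                                     gen$truth$dex0_ugml == 0)]]
  at_truth <- lma_refine(cond, truth, free = c("rho", "K"))
  expect_lt(at_truth$objective, 1e-8)
  expect_equal(at_truth$par[["rho"]], truth$rho, tolerance = 1e-4)
  expect_equal(at_truth$par[["K"]], truth$K, tolerance = 1e-4)

  start <- update_params(truth, rho = 1.15, K = 4.6)
  f_start <- carrgo_objective(start, cond)
  refined <- lma_refine(cond, start, free = c("rho", "K"))
  expect_lte(refined$objective, f_start)
  expect_equal(refined$par[["rho"]], truth$rho, tolerance = 1e-3)
  expect_error(lma_refine(cond, update_params(truth, rho = 100),
                          free = c("rho", "K")), "bounds")
})

test_that("single-condition PSO+LM fit recovers logistic growth parameters", {
  gen <- small_staged_dataset(seed = 7)
  cond <- condition_data(gen$data, "SYN-GBM-1", NA, 0)
  base <- carrgo_params(rho = 3, K = 12, kappa1 = 1, kappa2 = 1, theta = 0.5)
  ft <- fit_condition(cond, base, free = c("rho", "K"), seed = 42,
                      control = fast_control())
  expect_equal(ft$par[["rho"]], 1, tolerance = 1e-3)
  expect_equal(ft$par[["K"]], 5, tolerance = 1e-3)
  expect_true(ft$converged)
})

test_that("staged protocol flags missing condition types instead of failing", {
  gen <- small_staged_dataset(seed = 7)
  cart_only <- dplyr::filter(gen$data, !is.na(et_ratio))
  fit <- staged_fit(cart_only, seed = 1,
                    control = fast_control(n_particles = 5, iters = 5))
  expect_null(fit$stage1)
  expect_true(any(grepl("stage1", fit$skipped)))
  expect_true(any(grepl("requires stage", fit$skipped)))
  expect_equal(nrow(fit$stage3), 0)
})

test_that("fits are invariant to duplicate averaging order and tidy/glance work", {
  gen <- small_staged_dataset(seed = 7)
  fit <- staged_fit(gen$data, seed = 5,
                    control = fast_control(n_particles = 10, iters = 15))
  td <- tidy(fit)
  expect_true(all(c("stage", "term", "estimate") %in% names(td)))
  expect_setequal(
    td$term[td$stage == 4],
    c("kappa1", "kappa2", "theta", "c3"))
  gl <- glance(fit)
  expect_equal(gl$seed, 5)
  expect_equal(gl$n_stage4, 1)
  # objective stored equals objective re-evaluated at the estimates
  cond <- condition_data(gen$data, "SYN-GBM-1", NA, 0)
  p_hat <- carrgo_params(rho = fit$stage1$rho, K = fit$stage1$K,
                         kappa1 = 1, kappa2 = 1, theta = 0.5)
  expect_equal(carrgo_objective(p_hat, cond), fit$stage1$objective,
               tolerance = 1e-6)
})

test_that("fitted condition parameter sets assemble the staged estimates", {
  gen <- small_staged_dataset(seed = 7)
  fit <- staged_fit(gen$data, seed = 5,
                    control = fast_control(n_particles = 10, iters = 15))
  fp <- fitted_condition_params(fit)
  expect_equal(nrow(fp), 2)  # one no-Dex E:T fit + one Dex condition fit
  p4 <- fp$params[[which(fp$dex0_ugml > 0)]]
  expect_equal(p4$rho, fit$stage1$rho)
  expect_equal(p4$c3, fit$stage4$c3[1])
  expect_equal(p4$D0, 1e-3)
})
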