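test_that("equilibria take their closed forms and annihilate the rhs", {
  p <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 0.5)
  eq <- equilibria(p, 0)
  expect_equal(eq$x_star, c(0, 1, 0.5))
  expect_equal(eq$y_star, c(0, 0, 0.5))
  # tumor coordinate of coexistence is theta/kappa2
  p2 <- carrgo_params(1, 1, 1, kappa2 = 1, theta = 0.4)
  eq2 <- equilibria(p2, 0)
  expect_equal(eq2$x_star[eq2$label == "coexistence"], 0.4)
  # theta = 0: tumor death as the coexistence equilibrium
  p3 <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 0)
  eq3 <- equilibria(p3, 0)
  expect_equal(eq3$x_star[3], 0)
  expect_equal(eq3$y_star[3], 1)  # rho/kappa1

  set.seed(3)
  for (p in rand_params(20, with_dex = TRUE)) {
    for (tt in c(0, 0.2, 1)) {
      eq <- equilibria(p, tt)
      for (i in 1:3) {
        d <- rhs_nonautonomous(p, tt, eq$x_star[i], eq$y_star[i])
        expect_equal(unname(d), c(0, 0), tolerance = 1e-9)
      }
    }
  }
  expect_error(equilibria(carrgo_params(1, 1, 0, 1, 0.5), 0), "kappa1")
})

test_that("closed-form eigenvalues match the hand example and the Jacobian", {
  p <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 0.5)
  ev <- coexistence_eigenvalues(p, 0)
  expect_equal(ev$lambda_plus, complex(real = -0.25,
                                       imaginary = 0.25 * sqrt(3)),
               tolerance = 1e-12)
  expect_equal(ev$discriminant, -3)

  set.seed(9)
  for (p in rand_params(300, with_dex = TRUE)) {
    tt <- runif(1, 0, 1.5)
    ev <- coexistence_eigenvalues(p, tt)
    lam <- sort(c(ev$lambda_plus, ev$lambda_minus))
    num <- sort(as.complex(eigen(coexistence_jacobian(p, tt),
                                 only.values = TRUE)$values))
    expect_equal(lam, num, tolerance = 1e-9)
  }
})

test_that("trace and determinant identities hold", {
  set.seed(13)
  for (p in rand_params(100, with_dex = TRUE)) {
    tt <- runif(1, 0, 1)
    er <- effective_rates(p, tt)
    ev <- coexistence_eigenvalues(p, tt)
    expect_equal(Re(ev$lambda_plus + ev$lambda_minus),
                 -er$rho_t * er$theta_t / (p$kappa2 * er$K_t),
                 tolerance = 1e-9)
    expect_equal(Re(ev$lambda_plus * ev$lambda_minus),
                 er$theta_t * er$rho_t *
                   (er$K_t * p$kappa2 - er$theta_t) / (er$K_t * p$kappa2),
                 tolerance = 1e-9)
  }
})

test_that("eigenvalues do not depend on the killing rate kappa1", {
  set.seed(17)
  for (p in rand_params(50, with_dex = TRUE)) {
    p2 <- update_params(p, kappa1 = p$kappa1 * 7.3)
    ev1 <- coexistence_eigenvalues(p, 0.4)
    ev2 <- coexistence_eigenvalues(p2, 0.4)
    expect_equal(ev1$lambda_plus, ev2$lambda_plus, tolerance = 1e-12)
    expect_equal(ev1$lambda_minus, ev2$lambda_minus, tolerance = 1e-12)
  }
})

test_that("oscillation test is equivalent to a non-zero imaginary part", {
  p <- carrgo_params(1, 1, 1, 1, 0.5)
  expect_true(oscillation_test(p, 0))
  # theta(t) >= kappa2 K(t): discriminant >= 1, no oscillation
  p2 <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 1.5)
  expect_false(oscillation_test(p2, 0))
  # theta -> 0+: strongly oscillatory
  p3 <- carrgo_params(1, 1, 1, 1, theta = 1e-9)
  expect_true(oscillation_test(p3, 0))

  set.seed(23)
  for (p in rand_params(200, with_dex = TRUE)) {
    tt <- runif(1, 0, 1)
    ev <- coexistence_eigenvalues(p, tt)
    expect_identical(oscillation_test(p, tt), Im(ev$lambda_plus) != 0)
  }
})

test_that("stable spirals whenever theta(t) > 0 and the state oscillates", {
  set.seed(29)
  for (p in rand_params(200, with_dex = TRUE)) {
    tt <- runif(1, 0, 2)
    er <- effective_rates(p, tt)
    if (er$theta_t > 0 && er$rho_t > 0 && oscillation_test(p, tt)) {
      ev <- coexistence_eigenvalues(p, tt)
      expect_lt(Re(ev$lambda_plus), 0)
    }
  }
})

test_that("the singular point theta(t) = 0 falls back to the numeric Jacobian", {
  p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 1, theta = 0.5,
                     c3 = -0.5, sigma = 5, D0 = 0.1)
  ev <- coexistence_eigenvalues(p, 0)  # theta(0) = 0.5 - 0.5 = 0
  expect_true(is.na(ev$discriminant))
  expect_equal(ev$lambda_plus, as.complex(0), tolerance = 1e-12)
})

test_that("Hopf crossings are found where and only where stability flips", {
  # no Dex effect: eigenvalues time-independent, no crossings
  p0 <- carrgo_params(1, 5, 2, 1, 0.25)
  expect_length(hopf_times(p0, 4), 0)

  # c3 < -theta: initially unstable, restabilises when theta(t) crosses 0,
  # analytically at t = log(-c3/theta)/sigma
  p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 0.8, theta = 0.6,
                     c3 = -2.4, sigma = 5, D0 = 0.1)
  expect_gt(max(Re(coexistence_eigenvalues(p, 0)$lambda_plus),
                Re(coexistence_eigenvalues(p, 0)$lambda_minus)), 0)
  ht <- hopf_times(p, 2)
  expect_length(ht, 1)
  expect_equal(ht, log(2.4 / 0.6) / 5, tolerance = 1e-5)

  set.seed(31)
  for (i in 1:10) {
    theta <- runif(1, 0.1, 1)
    p <- carrgo_params(rho = runif(1, 0.5, 3), K = runif(1, 2, 10),
                       kappa1 = 2, kappa2 = runif(1, 0.3, 1.5),
                       theta = theta, c3 = -theta * runif(1, 1.5, 8),
                       sigma = 5, D0 = 0.1)
    ht <- hopf_times(p, 3)
    expect_length(ht, 1)
    expect_equal(ht, log(-p$c3 / p$theta) / 5, tolerance = 1e-4)
  }
})

test_that("bifurcation diagram labels are consistent with the crossings", {
  p0 <- carrgo_params(1, 5, 2, 1, 0.25)
  bd0 <- bifurcation_diagram(p0, seq(0, 48, 0.5))
  expect_length(unique(bd0$label), 1)

  p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 0.8, theta = 0.6,
                     c3 = -2.4, sigma = 5, D0 = 0.1)
  bd <- bifurcation_diagram(p, seq(0, 72, 0.25))
  hopf <- attr(bd, "hopf_times_hr")
  expect_length(hopf, 1)
  stable <- grepl("^stable", bd$label)
  flips <- which(diff(stable) != 0)
  expect_length(flips, 1)
  expect_lt(abs(bd$time_hr[flips] - hopf), 0.5)
  # once the drug has cleared (>> 5 half-lives) the spiral is stable
  expect_equal(bd$label[nrow(bd)], "stable_spiral")
  expect_true(all(stable[bd$time_hr > 24]))
})

test_that("three-species spectrum is the pair plus the clearance rate", {
  p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 0.8, theta = 0.6,
                     c3 = -2.4, sigma = 5, D0 = 0.1)
  ev3 <- autonomous_coexistence_eigenvalues(p, D = 0)
  ev2 <- coexistence_eigenvalues(p, t = 1e9)
  expect_equal(sort(Re(ev3))[1], -5)  # the clearance eigenvalue, -sigma
  expect_equal(sort(ev3[order(-Re(ev3))][1:2]),
               sort(c(ev2$lambda_plus, ev2$lambda_minus)), tolerance = 1e-9)

  # frozen-D correspondence with the nonautonomous pair at D = D0 e^{-sigma t}
  set.seed(37)
  for (p in rand_params(30, with_dex = TRUE)) {
    tt <- runif(1, 0, 1)
    ev3 <- autonomous_coexistence_eigenvalues(p, dex_concentration(p, tt))
    ev2 <- coexistence_eigenvalues(p, tt)
    pair <- ev3[-which.min(abs(ev3 + p$sigma))]  # drop the -sigma eigenvalue
    expect_equal(sort(pair),
                 sort(c(ev2$lambda_plus, ev2$lambda_minus)),
                 tolerance = 1e-8)
  }
})

test_that("death and proliferation equilibria are never the stable state", {
  # the CAR-T-free Jacobians: death has eigenvalue rho(t) > 0, tumor
  # proliferation has eigenvalue kappa2 K(t) - theta(t); whenever the
  # coexistence point lies in the quadrant the latter is positive too
  set.seed(41)
  for (p in rand_params(100, with_dex = FALSE)) {
    er <- effective_rates(p, 0)
    expect_gt(er$rho_t, 0)
    eq <- equilibria(p, 0)
    if (all(eq$in_quadrant)) {
      expect_gt(p$kappa2 * er$K_t - er$theta_t, -1e-12)
    }
  }
})

test_that("bifurcation CSV export has the documented schema", {
  p <- carrgo_params(1, 5, 2, 1, 0.25, c3 = 0.3, sigma = 5, D0 = 0.01)
  bd <- bifurcation_diagram(p, seq(0, 24, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bifurcation(bd, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("time_hr", "re_lambda_plus", "im_lambda_plus",
                 "re_lambda_minus", "im_lambda_minus", "label",
                 "x_star", "y_star"))
})
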