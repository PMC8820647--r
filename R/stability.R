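# Time-resolved stability analysis of the nonautonomous system. Because the
# Dex forcing is a bounded, continuously differentiable exponential decay,
# the instantaneous (frozen-time) equilibria and Jacobian eigenvalues govern
# the transient dynamics, and time acts as the bifurcation parameter.

eff <- function(params, t) {
  decay <- exp(-params$sigma * t)
  rho_t <- params$rho - params$c0 * decay
  list(rho_t = rho_t,
       K_t = rho_t * params$K / params$rho,
       theta_t = params$theta + params$c3 * decay)
}

#' Instantaneous equilibria of the nonautonomous system
#'
#' Returns the three frozen-time equilibria at time `t`: death `(0, 0)`,
#' tumor proliferation `(K(t), 0)`, and coexistence
#' \eqn{(\theta(t)/\kappa_2,\; \rho(t)(K(t)\kappa_2 - \theta(t)) /
#' (K(t)\kappa_1\kappa_2))}. The coexistence point may leave the
#' non-negative quadrant (e.g. when \eqn{\theta(t) < 0} under strongly
#' pro-proliferative Dex); it is reported as-is with `in_quadrant = FALSE`.
#'
#' @param params A [carrgo_params()] object with `rho > 0` and
#'   `kappa1, kappa2 > 0`.
#' @param t Time since treatment, days (scalar).
#' @return A tibble with columns `label`, `x_star`, `y_star`, `t`,
#'   `in_quadrant`.
#' @examples
#' p <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 0.5)
#' equilibria(p, t = 0)
#' @export
equilibria <- function(params, t = 0) {
  stopifnot(inherits(params, "carrgo_params"), length(t) == 1L)
  if (params$rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (params$kappa1 <= 0 || params$kappa2 <= 0) {
    stop("coexistence equilibrium requires `kappa1` > 0 and `kappa2` > 0",
         call. = FALSE)
  }
  e <- eff(params, t)
  x3 <- e$theta_t / params$kappa2
  y3 <- e$rho_t * (e$K_t * params$kappa2 - e$theta_t) /
    (e$K_t * params$kappa1 * params$kappa2)
  out <- tibble(
    label = c("death", "tumor_proliferation", "coexistence"),
    x_star = c(0, e$K_t, x3),
    y_star = c(0, 0, y3),
    t = t
  )
  out$in_quadrant <- out$x_star >= 0 & out$y_star >= 0
  out
}

# closed-form lambda+/- of the coexistence Jacobian; theta(t)=0 falls back
# to the numeric 2x2 eigen-decomposition (the formula divides by theta(t))
eigen_closed_form <- function(params, t) {
  e <- eff(params, t)
  if (e$theta_t == 0) {
    ev <- eigen(coexistence_jacobian(params, t), only.values = TRUE)$values
    ev <- as.complex(ev)
    lp <- ev[order(-Re(ev))][1]; lm <- ev[order(-Re(ev))][2]
    return(list(lambda_plus = lp, lambda_minus = lm, discriminant = NA_real_))
  }
  pref <- e$rho_t * e$theta_t / (2 * params$kappa2 * e$K_t)
  # 4*kappa2*K(t)/rho(t) == 4*kappa2*K/rho exactly
  rad <- 1 + (4 * params$kappa2 * params$K / params$rho) *
    (1 - params$kappa2 * e$K_t / e$theta_t)
  root <- sqrt(as.complex(rad))
  list(lambda_plus = pref * (-1 + root),
       lambda_minus = pref * (-1 - root),
       discriminant = rad)
}

#' Jacobian of the two-species system at the coexistence equilibrium
#'
#' The analytic 2x2 matrix
#' \eqn{[[-\rho(t) x^*/K(t), -\kappa_1 x^*], [\kappa_2 y^*, 0]]},
#' with \eqn{\rho(t)/K(t) = \rho/K} used for the (1,1) entry.
#'
#' @inheritParams equilibria
#' @return A 2x2 numeric matrix.
#' @export
coexistence_jacobian <- function(params, t = 0) {
  stopifnot(inherits(params, "carrgo_params"), length(t) == 1L)
  eq <- equilibria(params, t)
  x3 <- eq$x_star[eq$label == "coexistence"]
  y3 <- eq$y_star[eq$label == "coexistence"]
  matrix(c(-(params$rho / params$K) * x3, -params$kappa1 * x3,
           params$kappa2 * y3, 0),
         nrow = 2, byrow = TRUE)
}

#' Eigenvalues of the coexistence equilibrium over time
#'
#' Closed-form eigenvalue pair
#' \deqn{\lambda_\pm = \frac{\rho(t)\theta(t)}{2\kappa_2 K(t)}
#'   \left\{-1 \pm \left[1 + \frac{4\kappa_2 K(t)}{\rho(t)}
#'   \left(1 - \frac{\kappa_2 K(t)}{\theta(t)}\right)\right]^{1/2}\right\}}
#' evaluated at each requested time. The complex branch is taken when the
#' bracketed discriminant is negative (oscillatory regime). At the singular
#' point \eqn{\theta(t) = 0} the eigenvalues are computed from the numeric
#' Jacobian instead (`discriminant` is `NA` there).
#'
#' @param params A [carrgo_params()] object (`rho, K, kappa2 > 0`).
#' @param t Times since treatment, days (vectorised).
#' @return A tibble with columns `t`, `lambda_plus`, `lambda_minus`
#'   (complex), `discriminant`.
#' @examples
#' p <- carrgo_params(rho = 1, K = 1, kappa1 = 1, kappa2 = 1, theta = 0.5)
#' coexistence_eigenvalues(p, 0)  # -0.25 +/- 0.25*sqrt(3) i
#' @export
coexistence_eigenvalues <- function(params, t) {
  stopifnot(inherits(params, "carrgo_params"))
  if (params$rho <= 0 || params$K <= 0 || params$kappa2 <= 0) {
    stop("`rho`, `K` and `kappa2` must be > 0", call. = FALSE)
  }
  res <- lapply(t, function(tt) eigen_closed_form(params, tt))
  tibble(
    t = t,
    lambda_plus = vapply(res, function(r) r$lambda_plus, complex(1)),
    lambda_minus = vapply(res, function(r) r$lambda_minus, complex(1)),
    discriminant = vapply(res, function(r) r$discriminant, numeric(1))
  )
}

#' Does the coexistence equilibrium oscillate at time t?
#'
#' `TRUE` iff the eigenvalue pair has a non-zero imaginary part, i.e. the
#' closed-form discriminant is negative. This is the spiral/oscillation
#' condition; whether the oscillation is damped (stable) or growing is
#' decided by the sign of the shared real part.
#'
#' @inheritParams coexistence_eigenvalues
#' @return Logical vector, one element per time.
#' @export
oscillation_test <- function(params, t) {
  ev <- coexistence_eigenvalues(params, t)
  ifelse(is.na(ev$discriminant),
         Im(ev$lambda_plus) != 0,
         ev$discriminant < 0)
}

max_re_lambda <- function(params, t) {
  r <- eigen_closed_form(params, t)
  max(Re(r$lambda_plus), Re(r$lambda_minus))
}

#' Hopf crossing times of the coexistence equilibrium
#'
#' Finds all times in `(0, t_max]` where the largest real part of the
#' coexistence eigenvalues changes sign, i.e. where stability is gained or
#' lost as Dex clears. Sign changes are bracketed on a uniform grid and
#' refined by bisection to `tol` days. With `c0 = c3 = 0` the eigenvalues
#' are time-independent and the result is empty.
#'
#' @param params A [carrgo_params()] object.
#' @param t_max Horizon, days (> 0).
#' @param n_grid Number of bracketing intervals (default 1000).
#' @param tol Root refinement tolerance, days.
#' @return Numeric vector of crossing times in days (possibly empty).
#' @examples
#' # pro-proliferative Dex strong enough that c3 < -theta: initially
#' # unstable, restabilises as the drug clears
#' p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 0.8, theta = 0.6,
#'                    c3 = -2.4, sigma = 5)
#' hopf_times(p, t_max = 2) * 24  # hours; analytically log(4)/5 days
#' @export
hopf_times <- function(params, t_max, n_grid = 1000, tol = 1e-6) {
  stopifnot(inherits(params, "carrgo_params"), t_max > 0)
  grid <- seq(0, t_max, length.out = n_grid + 1)
  g <- vapply(grid, function(tt) max_re_lambda(params, tt), numeric(1))
  crossings <- numeric(0)
  s <- sign(g)
  for (i in seq_len(n_grid)) {
    if (s[i] == 0) next  # exact grid zero; neighbouring brackets catch flips
    if (s[i + 1] != 0 && s[i] != s[i + 1]) {
      root <- stats::uniroot(function(tt) max_re_lambda(params, tt),
                             lower = grid[i], upper = grid[i + 1],
                             tol = tol)$root
      crossings <- c(crossings, root)
    }
  }
  crossings
}

label_state <- function(lp, lm, tol = 1e-10) {
  oscillatory <- Im(lp) != 0
  re_max <- max(Re(lp), Re(lm))
  if (abs(re_max) <= tol) return("limit_cycle_crossing")
  if (oscillatory) {
    if (re_max < 0) "stable_spiral" else "unstable_spiral"
  } else {
    if (re_max < 0) "stable_node" else "unstable"
  }
}

#' Bifurcation diagram of the coexistence equilibrium over time
#'
#' Tabulates the coexistence eigenvalue pair, a stability label, and the
#' equilibrium path on a time grid, and records the Hopf crossing times.
#' Labels are `stable_spiral`, `unstable_spiral`, `stable_node`,
#' `unstable`, or `limit_cycle_crossing` (real part within `1e-10`/day of
#' zero).
#'
#' @param params A [carrgo_params()] object.
#' @param times Increasing time grid.
#' @param unit Unit of `times`: `"hours"` (default) or `"days"`.
#' @return A tibble of class `carrgo_bifurcation` with columns `time_hr`,
#'   `re_lambda_plus`, `im_lambda_plus`, `re_lambda_minus`,
#'   `im_lambda_minus`, `oscillatory`, `label`, `x_star`, `y_star`, and an
#'   attribute `hopf_times_hr`.
#' @examples
#' p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 0.8, theta = 0.6,
#'                    c3 = -2.4, sigma = 5, D0 = 0.1)
#' bd <- bifurcation_diagram(p, seq(0, 48, by = 0.5))
#' attr(bd, "hopf_times_hr")
#' @export
bifurcation_diagram <- function(params, times, unit = c("hours", "days")) {
  stopifnot(inherits(params, "carrgo_params"))
  unit <- match.arg(unit)
  if (any(diff(times) <= 0)) stop("`times` must be increasing", call. = FALSE)
  t_day <- if (unit == "hours") hr_to_day(times) else times
  ev <- coexistence_eigenvalues(params, t_day)
  eqs <- lapply(t_day, function(tt) {
    e <- equilibria(params, tt)
    e[e$label == "coexistence", c("x_star", "y_star")]
  })
  out <- tibble(
    time_hr = day_to_hr(t_day),
    re_lambda_plus = Re(ev$lambda_plus),
    im_lambda_plus = Im(ev$lambda_plus),
    re_lambda_minus = Re(ev$lambda_minus),
    im_lambda_minus = Im(ev$lambda_minus),
    oscillatory = Im(ev$lambda_plus) != 0,
    label = vapply(seq_along(t_day), function(i)
      label_state(ev$lambda_plus[i], ev$lambda_minus[i]), character(1)),
    x_star = vapply(eqs, function(e) e$x_star, numeric(1)),
    y_star = vapply(eqs, function(e) e$y_star, numeric(1))
  )
  attr(out, "hopf_times_hr") <- day_to_hr(hopf_times(params,
                                                     t_max = max(t_day)))
  attr(out, "params") <- params
  class(out) <- c("carrgo_bifurcation", class(out))
  out
}

#' Write a bifurcation diagram to CSV
#'
#' @param bd A `carrgo_bifurcation` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bifurcation <- function(bd, path) {
  stopifnot(is.data.frame(bd))
  cols <- c("time_hr", "re_lambda_plus", "im_lambda_plus", "re_lambda_minus",
            "im_lambda_minus", "label", "x_star", "y_star")
  readr::write_csv(as_tibble(bd)[, cols], path)
  invisible(path)
}

#' Eigenvalues of the three-species autonomous system at coexistence
#'
#' Builds the 3x3 Jacobian of the autonomous formulation (tumor, CAR T-cell,
#' Dex) at the frozen-D coexistence point and returns its numeric
#' eigenvalues. The Dex row couples only to itself, so the spectrum is the
#' two-species pair together with \eqn{-\sigma}; at `D = 0` this reduces
#' exactly to the Dex-free coexistence eigenvalues plus the clearance rate.
#'
#' @param params A [carrgo_params()] object (unscaled Dex constants are
#'   derived as `c0 / D0`, `c3 / D0`; both zero when `D0 = 0`).
#' @param D Frozen Dex concentration, ug/ml.
#' @return Complex vector of length 3, sorted by decreasing real part.
#' @export
autonomous_coexistence_eigenvalues <- function(params, D = 0) {
  stopifnot(inherits(params, "carrgo_params"), length(D) == 1L, D >= 0)
  if (params$rho <= 0 || params$kappa1 <= 0 || params$kappa2 <= 0) {
    stop("`rho`, `kappa1`, `kappa2` must be > 0", call. = FALSE)
  }
  cc <- if (params$D0 > 0) unscaled_dex_constants(params) else c(0, 0)
  rho_D <- params$rho - cc[[1]] * D
  K_D <- rho_D * params$K / params$rho
  theta_D <- params$theta + cc[[2]] * D
  x3 <- theta_D / params$kappa2
  y3 <- rho_D * (K_D * params$kappa2 - theta_D) /
    (K_D * params$kappa1 * params$kappa2)
  J <- matrix(c(
    rho_D - 2 * (params$rho / params$K) * x3 - params$kappa1 * y3,
    -params$kappa1 * x3, -cc[[1]] * x3,
    params$kappa2 * y3,
    params$kappa2 * x3 - theta_D, -cc[[2]] * y3,
    0, 0, -params$sigma
  ), nrow = 3, byrow = TRUE)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  ev[order(-Re(ev), -Im(ev))]
}
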