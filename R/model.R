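#' Right-hand side of the three-species autonomous system
#'
#' Evaluates the mass-action system in which dexamethasone is an explicit
#' state variable:
#' \deqn{dx/dt = \rho x - (\rho/K) x^2 - \kappa_1 x y - c_0' D x}
#' \deqn{dy/dt = \kappa_2 x y - \theta y - c_3' D y}
#' \deqn{dD/dt = -\sigma D}
#' where \eqn{c_0', c_3'} are the *unscaled* interaction constants
#' (`params$c0 / params$D0` etc., see [unscaled_dex_constants()]). When
#' `D0 = 0` the Dex terms vanish and the unscaled constants are taken as 0.
#'
#' @param params A [carrgo_params()] object.
#' @param x,y Tumor and CAR T-cell populations, CI.
#' @param D Dex concentration, ug/ml.
#' @return Named numeric vector `c(dx, dy, dD)` (vectorised over states of
#'   equal length, returned as a tibble when length > 1).
#' @export
rhs_autonomous <- function(params, x, y, D) {
  stopifnot(inherits(params, "carrgo_params"))
  cc <- if (params$D0 > 0) unscaled_dex_constants(params) else c(0, 0)
  dx <- params$rho * x - (params$rho / params$K) * x^2 -
    params$kappa1 * x * y - cc[[1]] * D * x
  dy <- params$kappa2 * x * y - params$theta * y - cc[[2]] * D * y
  dD <- -params$sigma * D
  if (length(x) > 1L) tibble(dx = dx, dy = dy, dD = dD)
  else c(dx = dx, dy = dy, dD = dD)
}

#' Right-hand side of the two-species nonautonomous system
#'
#' The canonical formulation after substituting \eqn{D(t) = D_0 e^{-\sigma t}}
#' and rescaling the Dex constants:
#' \deqn{dx/dt = \rho(t) x (1 - x / K(t)) - \kappa_1 x y}
#' \deqn{dy/dt = \kappa_2 x y - \theta(t) y.}
#' The logistic term is evaluated as \eqn{\rho(t) x - (\rho/K) x^2}, using
#' the exact identity \eqn{\rho(t)/K(t) = \rho/K}, which keeps the vector
#' field well defined even at times where \eqn{K(t)} passes through zero.
#'
#' @param params A [carrgo_params()] object with `rho > 0`.
#' @param t Time since treatment, days.
#' @param x,y Tumor and CAR T-cell populations, CI.
#' @return Named numeric vector `c(dx, dy)`, or a tibble when vectorised.
#' @export
rhs_nonautonomous <- function(params, t, x, y) {
  stopifnot(inherits(params, "carrgo_params"))
  if (params$rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  decay <- exp(-params$sigma * t)
  rho_t <- params$rho - params$c0 * decay
  theta_t <- params$theta + params$c3 * decay
  dx <- rho_t * x - (params$rho / params$K) * x^2 - params$kappa1 * x * y
  dy <- params$kappa2 * x * y - theta_t * y
  if (length(x) > 1L || length(t) > 1L) tibble(dx = dx, dy = dy)
  else c(dx = dx, dy = dy)
}
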