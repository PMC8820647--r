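#' Model parameters for the CAR T-cell / tumor / dexamethasone system
#'
#' Bundles the constants of the predator-prey model of tumor cells (prey,
#' measured in cell index, CI) and CAR T-cells (predator, CI) under an
#' exponentially clearing dexamethasone (Dex) concentration
#' \eqn{D(t) = D_0 e^{-\sigma t}}.
#'
#' The canonical formulation is the nonautonomous two-species system
#' \deqn{dx/dt = \rho(t)\,x\,(1 - x/K(t)) - \kappa_1 x y}
#' \deqn{dy/dt = \kappa_2 x y - \theta(t)\, y}
#' with effective rates
#' \eqn{\rho(t) = \rho - c_0 e^{-\sigma t}},
#' \eqn{K(t) = \rho(t) K / \rho}, and
#' \eqn{\theta(t) = \theta + c_3 e^{-\sigma t}}.
#' Here `c0` and `c3` are the *rescaled* Dex interaction constants: the
#' initial concentration \eqn{D_0} is absorbed into them, so they carry units
#' of day\eqn{^{-1}} regardless of dose. The equivalent three-species
#' autonomous formulation uses unscaled constants \eqn{c' = c / D_0} (see
#' [rhs_autonomous()]); the absorption convention is an explicit choice of
#' this package and is applied consistently throughout.
#'
#' Signs of `c0` and `c3` are unconstrained: Dex may be anti-proliferative
#' (`c0 > 0` lowers the effective tumor growth rate and carrying capacity;
#' `c3 > 0` raises CAR T-cell death) or pro-proliferative (negative values).
#'
#' @param rho Tumor cell net growth rate, day^-1 (>= 0; must be > 0 wherever
#'   the effective carrying capacity `K(t)` is evaluated).
#' @param K Tumor carrying capacity, CI (>= 0).
#' @param kappa1 Tumor killing rate, day^-1 CI^-1 (>= 0).
#' @param kappa2 Net CAR T-cell proliferation/exhaustion rate when stimulated
#'   by tumor cells, day^-1 CI^-1 (>= 0).
#' @param theta CAR T-cell death rate, day^-1 (>= 0).
#' @param c0 Effect of Dex on tumor growth, day^-1, rescaled (any sign).
#' @param c3 Effect of Dex on CAR T-cell death, day^-1, rescaled (any sign).
#' @param sigma Dex clearance rate, day^-1 (>= 0). Default 5/day, the value
#'   implied by a plasma half-life of about 200 minutes.
#' @param D0 Initial Dex concentration, ug/ml (>= 0).
#'
#' @return An object of class `carrgo_params`: a named list of the nine
#'   constants.
#' @examples
#' p <- carrgo_params(rho = 1, K = 5, kappa1 = 2, kappa2 = 1, theta = 0.3)
#' p
#' @seealso [dex_concentration()], [effective_rates()], [carrgo_simulate()]
#' @export
carrgo_params <- function(rho, K, kappa1, kappa2, theta,
                          c0 = 0, c3 = 0, sigma = 5, D0 = 0) {
  p <- list(rho = rho, K = K, kappa1 = kappa1, kappa2 = kappa2,
            theta = theta, c0 = c0, c3 = c3, sigma = sigma, D0 = D0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  nonneg <- c("rho", "K", "kappa1", "kappa2", "theta", "sigma", "D0")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) ", paste0("`", bad, "`", collapse = ", "),
         " must be non-negative", call. = FALSE)
  }
  structure(p, class = "carrgo_params")
}

#' @export
print.carrgo_params <- function(x, ...) {
  cat("<carrgo_params>\n")
  cat(sprintf("  rho    = %g /day   K  = %g CI\n", x$rho, x$K))
  cat(sprintf("  kappa1 = %g /day/CI  kappa2 = %g /day/CI  theta = %g /day\n",
              x$kappa1, x$kappa2, x$theta))
  cat(sprintf("  c0 = %g /day  c3 = %g /day  (rescaled Dex effects)\n",
              x$c0, x$c3))
  cat(sprintf("  sigma = %g /day  D0 = %g ug/ml\n", x$sigma, x$D0))
  invisible(x)
}

#' @export
as.list.carrgo_params <- function(x, ...) unclass(x)

#' Update selected fields of a parameter set
#'
#' @param params A [carrgo_params()] object.
#' @param ... Named scalar replacements (e.g. `theta = 0.6`).
#' @return A revalidated `carrgo_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "carrgo_params"))
  repl <- list(...)
  p <- unclass(params)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(repl)] <- repl
  do.call(carrgo_params, p)
}

#' Dexamethasone concentration at time t
#'
#' Closed-form single-compartment clearance \eqn{D(t) = D_0 e^{-\sigma t}}.
#'
#' @param params A [carrgo_params()] object (uses `D0`, `sigma`).
#' @param t Time since treatment, days (vectorised, all >= 0).
#' @return Concentration(s) in ug/ml.
#' @examples
#' p <- carrgo_params(1, 5, 2, 1, 0.3, sigma = 5, D0 = 1)
#' dex_concentration(p, c(0, log(2) / 5))  # 1, then half after ~200 min
#' @export
dex_concentration <- function(params, t) {
  stopifnot(inherits(params, "carrgo_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative (days since treatment)",
         call. = FALSE)
  }
  params$D0 * exp(-params$sigma * t)
}

#' Dex clearance rate implied by a plasma half-life
#'
#' @param half_life_min Half-life in minutes (default 200, the reported
#'   plasma half-life of dexamethasone).
#' @return Clearance rate in day^-1 (`log(2) / half-life`), about 5/day for
#'   the default.
#' @export
dex_clearance_rate <- function(half_life_min = 200) {
  stopifnot(is.numeric(half_life_min), half_life_min > 0)
  log(2) / (half_life_min / 60 / 24)
}

#' Time-dependent effective rates of the nonautonomous model
#'
#' Evaluates \eqn{\rho(t) = \rho - c_0 e^{-\sigma t}},
#' \eqn{K(t) = \rho(t) K / \rho}, and
#' \eqn{\theta(t) = \theta + c_3 e^{-\sigma t}}. By construction
#' \eqn{K(t)/\rho(t) = K/\rho} for all t, and all three rates converge to
#' their Dex-free values as the drug clears.
#'
#' @param params A [carrgo_params()] object with `rho > 0`.
#' @param t Time(s) since treatment, days.
#' @return A tibble with columns `t`, `rho_t`, `K_t`, `theta_t` (one row
#'   per time point).
#' @examples
#' p <- carrgo_params(rho = 2, K = 2, kappa1 = 1, kappa2 = 1, theta = 1,
#'                    c0 = 0.5, sigma = 5)
#' effective_rates(p, c(0, 1, 10))
#' @export
effective_rates <- function(params, t) {
  stopifnot(inherits(params, "carrgo_params"))
  if (params$rho <= 0) {
    stop("effective carrying capacity K(t) requires `rho` > 0", call. = FALSE)
  }
  decay <- exp(-params$sigma * t)
  rho_t <- params$rho - params$c0 * decay
  tibble(
    t = t,
    rho_t = rho_t,
    K_t = rho_t * params$K / params$rho,
    theta_t = params$theta + params$c3 * decay
  )
}

#' Convert rescaled Dex constants to unscaled (autonomous-form) constants
#'
#' The stored `c0`, `c3` absorb the initial dose `D0`; the three-species
#' autonomous formulation multiplies its constants by the instantaneous
#' concentration `D` instead, so `c' = c / D0`.
#'
#' @param params A [carrgo_params()] object with `D0 > 0`.
#' @return Named numeric vector `c(c0_unscaled, c3_unscaled)`.
#' @export
unscaled_dex_constants <- function(params) {
  stopifnot(inherits(params, "carrgo_params"))
  if (params$D0 <= 0) {
    stop("unscaled constants require `D0` > 0 (no dose to absorb)",
         call. = FALSE)
  }
  c(c0_unscaled = params$c0 / params$D0, c3_unscaled = params$c3 / params$D0)
}
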