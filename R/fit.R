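#' Default parameter bounds for fitting
#'
#' Box constraints taken from the observed ranges of the model constants in
#' this assay system: `rho` in \[0.5, 12\] /day, `K` in \[1, 20\] CI,
#' `kappa1` in \[0.8, 90\] /day/CI, `kappa2` in \[0.1, 2\] /day/CI, `theta`
#' in \[1e-12, 3\] /day (kept strictly positive so the coexistence
#' eigenvalue formula stays regular), `c0` in \[-10, 4\] /day, `c3` in
#' \[-11, 11\] /day. The clearance rate `sigma` is fixed at 5/day and is
#' never a free parameter.
#'
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
default_bounds <- function() {
  list(
    lower = c(rho = 0.5, K = 1, kappa1 = 0.8, kappa2 = 0.1,
              theta = 1e-12, c0 = -10, c3 = -11),
    upper = c(rho = 12, K = 20, kappa1 = 90, kappa2 = 2,
              theta = 3, c0 = 4, c3 = 11)
  )
}

#' Optimizer and solver settings for fitting
#'
#' @param n_particles,iters Particle swarm size and iteration count.
#' @param rtol,atol ODE solver tolerances used inside the objective
#'   (looser than simulation defaults; the residual scale is set by
#'   measurement noise, not solver error).
#' @param penalty Finite objective value substituted when integration fails,
#'   so population-based search can continue.
#' @param lm_maxiter Maximum Levenberg-Marquardt iterations.
#' @param lm_starts Number of distinct swarm personal-best positions used
#'   as Levenberg-Marquardt starting points (multi-start guards against
#'   the swarm's global best sitting in a shallow local basin).
#' @param w_x Weight on tumor residuals.
#' @param w_y Weight on CAR T-cell endpoint residuals; `NULL` (default)
#'   uses `w_x * n_tumor / n_cart` so the two dense-vs-sparse species
#'   contribute comparably to the objective.
#' @return A named list of settings.
#' @export
fit_control <- function(n_particles = 50, iters = 200,
                        rtol = 1e-6, atol = 1e-8,
                        penalty = 1e10, lm_maxiter = 100, lm_starts = 5,
                        w_x = 1, w_y = NULL) {
  list(n_particles = n_particles, iters = iters, rtol = rtol, atol = atol,
       penalty = penalty, lm_maxiter = lm_maxiter, lm_starts = lm_starts,
       w_x = w_x, w_y = w_y)
}

cond_weights <- function(cond, control) {
  n_x <- nrow(cond$tumor)
  n_y <- nrow(cond$cart)
  w_y <- if (is.null(control$w_y)) {
    if (n_y > 0) control$w_x * n_x / n_y else 0
  } else control$w_y
  list(w_x = control$w_x, w_y = w_y)
}

# weighted residual vector for one condition; initial conditions are fixed
# to the measured values, CAR T-cells enter only via their two endpoints
cond_residuals <- function(params, cond, control = fit_control()) {
  t_all <- sort(unique(c(cond$tumor$time_hr, cond$cart$time_hr)))
  if (length(t_all) < 2L) stop("condition needs >= 2 time points",
                               call. = FALSE)
  sim <- carrgo_simulate(params, x0 = cond$x0, y0 = cond$y0,
                         times = t_all, unit = "hours",
                         rtol = control$rtol, atol = control$atol)
  w <- cond_weights(cond, control)
  ix <- match(cond$tumor$time_hr, t_all)
  res <- sqrt(w$w_x) * (sim$x_ci[ix] - cond$tumor$ci)
  if (nrow(cond$cart) > 0) {
    iy <- match(cond$cart$time_hr, t_all)
    res <- c(res, sqrt(w$w_y) * (sim$y_ci[iy] - cond$cart$ci))
  }
  res
}

#' Weighted sum-of-squares objective for one assay condition
#'
#' The fitting criterion: weighted squared error between the simulated and
#' measured tumor impedance series plus the two CAR T-cell endpoint
#' measurements. Integration failures return `control$penalty` (recorded as
#' an attribute) rather than erroring, so swarm-based search continues.
#'
#' @param params A [carrgo_params()] object; `D0` should equal the
#'   condition's initial Dex concentration.
#' @param cond An `assay_condition` from [condition_data()].
#' @param control A [fit_control()] list.
#' @return Non-negative scalar.
#' @export
carrgo_objective <- function(params, cond, control = fit_control()) {
  stopifnot(inherits(cond, "assay_condition"))
  res <- tryCatch(cond_residuals(params, cond, control),
                  error = function(e) NULL)
  if (is.null(res) || any(!is.finite(res))) {
    return(structure(control$penalty, failed = TRUE))
  }
  sum(res^2)
}

#' Levenberg-Marquardt refinement of a parameter estimate
#'
#' Polishes a rough (typically swarm-derived) estimate of the free
#' parameters by bounded Levenberg-Marquardt on the weighted residual
#' vector. The best iterate is returned even on non-convergence.
#'
#' @param cond An `assay_condition` from [condition_data()].
#' @param params A [carrgo_params()] object holding the starting values of
#'   the free parameters and the fixed values of the rest.
#' @param free Character vector of parameter names to refine.
#' @param bounds A [default_bounds()]-style list.
#' @param control A [fit_control()] list.
#' @return A list with `estimates` (a `carrgo_params`), `par` (named free
#'   values), `objective`, `converged`, `message`, `niter`.
#' @export
lma_refine <- function(cond, params, free, bounds = default_bounds(),
                       control = fit_control()) {
  stopifnot(inherits(params, "carrgo_params"), length(free) >= 1L,
            all(free %in% names(bounds$lower)))
  start <- unlist(unclass(params)[free])
  if (any(start < bounds$lower[free] - 1e-12) ||
      any(start > bounds$upper[free] + 1e-12)) {
    stop("starting values must lie within bounds", call. = FALSE)
  }
  resid_fn <- function(p) {
    pp <- do.call(update_params, c(list(params), as.list(setNames(p, free))))
    r <- tryCatch(cond_residuals(pp, cond, control), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) {
      rep(sqrt(control$penalty), nrow(cond$tumor) + nrow(cond$cart))
    } else r
  }
  f0 <- sum(resid_fn(start)^2)
  lm <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = bounds$lower[free], upper = bounds$upper[free],
    control = minpack.lm::nls.lm.control(maxiter = control$lm_maxiter)
  )
  par <- setNames(as.numeric(lm$par), free)
  fval <- lm$deviance
  if (!is.finite(fval) || fval > f0) {  # never accept a worse point
    par <- start
    fval <- f0
  }
  est <- do.call(update_params, c(list(params), as.list(par)))
  list(estimates = est, par = par, objective = fval,
       converged = lm$info %in% 1:4, message = lm$message,
       niter = lm$niter)
}

#' Fit selected parameters for one assay condition (PSO then LM)
#'
#' Global particle-swarm search over the free parameters inside the bounds,
#' followed by Levenberg-Marquardt refinement from the swarm optimum.
#'
#' @inheritParams lma_refine
#' @param params A `carrgo_params` carrying the fixed parameter values
#'   (free entries are ignored as starting values; the swarm explores the
#'   full box).
#' @param seed Integer seed for the swarm (required).
#' @return As [lma_refine()], plus `pso` diagnostics.
#' @export
fit_condition <- function(cond, params, free, seed,
                          bounds = default_bounds(),
                          control = fit_control()) {
  stopifnot(inherits(cond, "assay_condition"))
  obj_fn <- function(p) {
    pp <- do.call(update_params, c(list(params), as.list(setNames(p, free))))
    carrgo_objective(pp, cond, control)
  }
  pso <- pso_search(obj_fn, lower = bounds$lower[free],
                    upper = bounds$upper[free], seed = seed,
                    n_particles = control$n_particles,
                    iters = control$iters)
  # LM from the global best and next-best distinct personal bests, plus a
  # warm start at the supplied parameter values when they lie in the box
  # (in the staged protocol these carry the previous stage's estimates)
  starts <- unique(round(pso$pbest, 8))
  n_starts <- min(max(1L, control$lm_starts), nrow(starts))
  starts <- starts[seq_len(n_starts), , drop = FALSE]
  warm <- unlist(unclass(params)[free])
  if (all(warm >= bounds$lower[free]) && all(warm <= bounds$upper[free])) {
    starts <- rbind(starts, warm)
  }
  out <- NULL
  for (s in seq_len(nrow(starts))) {
    start_params <- do.call(
      update_params, c(list(params), as.list(setNames(starts[s, ], free))))
    cand <- lma_refine(cond, start_params, free, bounds, control)
    if (is.null(out) || cand$objective < out$objective) out <- cand
  }
  out$pso <- list(value = pso$value, iters = pso$iters,
                  n_evals = pso$n_evals)
  out
}

stage_seed <- function(seed, k) (seed + 9973L * k) %% .Machine$integer.max

#' Staged parameter estimation for one cell line
#'
#' Implements the four-stage identification protocol that makes every free
#' parameter measurable from the assay design:
#' \enumerate{
#'   \item tumor-only, no Dex: fit `rho`, `K` (logistic growth);
#'   \item tumor-only, with Dex (one fit per Dex level): fit the rescaled
#'     `c0` with `rho`, `K` fixed;
#'   \item tumor + CAR T-cells, no Dex (one fit per E:T ratio): fit
#'     `kappa1`, `kappa2`, `theta`;
#'   \item tumor + CAR T-cells, with Dex (one fit per E:T x Dex condition):
#'     fit `kappa1`, `kappa2`, `theta`, `c3`, with `rho`, `K` from stage 1
#'     and `c0` from the matching stage-2 Dex level.
#' }
#' Stage 4 refits the interaction parameters per condition because the
#' killing, proliferation/exhaustion, and death rates are observed to shift
#' between Dex and Dex-free conditions. Missing condition types cause the
#' dependent stages to be skipped and flagged, not to error.
#'
#' @param data A long-format assay tibble (see [validate_assay()]).
#' @param cell_line Cell line to fit; default the single line present.
#' @param seed Integer seed (required); per-stage seeds are derived from it
#'   and recorded.
#' @param bounds A [default_bounds()]-style list.
#' @param control A [fit_control()] list.
#' @param sigma Dex clearance rate, fixed (never fitted).
#' @return An object of class `carrgo_fit`; see [tidy.carrgo_fit()] and
#'   [glance.carrgo_fit()].
#' @export
staged_fit <- function(data, cell_line = NULL, seed,
                       bounds = default_bounds(),
                       control = fit_control(), sigma = 5) {
  data <- validate_assay(data)
  if (is.null(cell_line)) {
    lines <- unique(data$cell_line)
    if (length(lines) != 1L) {
      stop("multiple cell lines present; pass `cell_line`", call. = FALSE)
    }
    cell_line <- lines
  }
  data <- data[data$cell_line == cell_line, ]
  cond_tab <- conditions(data)
  skipped <- character(0)
  base <- carrgo_params(rho = 1, K = 5, kappa1 = 1, kappa2 = 1,
                        theta = 0.5, sigma = sigma)

  ## Stage 1: rho, K from tumor-only / no-Dex
  stage1 <- NULL
  has_s1 <- any(is.na(cond_tab$et_ratio) & cond_tab$dex0_ugml == 0)
  if (has_s1) {
    cond <- condition_data(data, cell_line, NA, 0)
    stage1 <- fit_condition(cond, base, c("rho", "K"),
                            seed = stage_seed(seed, 1L),
                            bounds = bounds, control = control)
  } else {
    skipped <- c(skipped, "stage1: no tumor-only/no-Dex condition")
  }

  ## Stage 2: c0 per Dex level from tumor-only / Dex
  stage2 <- tibble(dex0_ugml = numeric(), c0 = numeric(),
                   objective = numeric(), converged = logical())
  s2_levels <- cond_tab$dex0_ugml[is.na(cond_tab$et_ratio) &
                                    cond_tab$dex0_ugml > 0]
  if (!has_s1 && length(s2_levels)) {
    skipped <- c(skipped, "stage2: requires stage 1")
  } else if (has_s1) {
    if (!length(s2_levels)) {
      skipped <- c(skipped, "stage2: no tumor-only/Dex condition")
    }
    for (k in seq_along(s2_levels)) {
      d0 <- s2_levels[k]
      cond <- condition_data(data, cell_line, NA, d0)
      p0 <- update_params(stage1$estimates, D0 = d0)
      ft <- fit_condition(cond, p0, "c0", seed = stage_seed(seed, 10L + k),
                          bounds = bounds, control = control)
      stage2 <- dplyr::bind_rows(stage2, tibble(
        dex0_ugml = d0, c0 = ft$par[["c0"]],
        objective = ft$objective, converged = ft$converged))
    }
  }

  ## Stage 3: kappa1, kappa2, theta per E:T from CAR T / no-Dex
  stage3 <- tibble(et_ratio = character(), kappa1 = numeric(),
                   kappa2 = numeric(), theta = numeric(),
                   objective = numeric(), converged = logical())
  s3_ets <- cond_tab$et_ratio[!is.na(cond_tab$et_ratio) &
                                cond_tab$dex0_ugml == 0]
  if (!has_s1 && length(s3_ets)) {
    skipped <- c(skipped, "stage3: requires stage 1")
  } else if (has_s1) {
    if (!length(s3_ets)) {
      skipped <- c(skipped, "stage3: no CAR-T/no-Dex condition")
    }
    for (k in seq_along(s3_ets)) {
      et <- s3_ets[k]
      cond <- condition_data(data, cell_line, et, 0)
      ft <- fit_condition(cond, stage1$estimates,
                          c("kappa1", "kappa2", "theta"),
                          seed = stage_seed(seed, 100L + k),
                          bounds = bounds, control = control)
      stage3 <- dplyr::bind_rows(stage3, tibble(
        et_ratio = et, kappa1 = ft$par[["kappa1"]],
        kappa2 = ft$par[["kappa2"]], theta = ft$par[["theta"]],
        objective = ft$objective, converged = ft$converged))
    }
  }

  ## Stage 4: kappa1, kappa2, theta, c3 per E:T x Dex condition
  stage4 <- tibble(et_ratio = character(), dex0_ugml = numeric(),
                   kappa1 = numeric(), kappa2 = numeric(),
                   theta = numeric(), c3 = numeric(),
                   objective = numeric(), converged = logical())
  s4 <- cond_tab[!is.na(cond_tab$et_ratio) & cond_tab$dex0_ugml > 0, ]
  if (nrow(s4) > 0 && (!has_s1 || nrow(stage3) == 0)) {
    skipped <- c(skipped, "stage4: requires stages 1 and 3")
  } else if (has_s1) {
    for (k in seq_len(nrow(s4))) {
      et <- s4$et_ratio[k]
      d0 <- s4$dex0_ugml[k]
      c0_row <- stage2[stage2$dex0_ugml == d0, ]
      if (nrow(c0_row) == 0) {
        skipped <- c(skipped, sprintf(
          "stage4 (%s, %g ug/ml): no matching stage-2 c0", et, d0))
        next
      }
      cond <- condition_data(data, cell_line, et, d0)
      s3_row <- stage3[stage3$et_ratio == et, ]
      p0 <- update_params(stage1$estimates, c0 = c0_row$c0[1], D0 = d0)
      if (nrow(s3_row) > 0) {
        p0 <- update_params(p0, kappa1 = s3_row$kappa1[1],
                            kappa2 = s3_row$kappa2[1],
                            theta = s3_row$theta[1])
      }
      ft <- fit_condition(cond, p0, c("kappa1", "kappa2", "theta", "c3"),
                          seed = stage_seed(seed, 1000L + k),
                          bounds = bounds, control = control)
      stage4 <- dplyr::bind_rows(stage4, tibble(
        et_ratio = et, dex0_ugml = d0,
        kappa1 = ft$par[["kappa1"]], kappa2 = ft$par[["kappa2"]],
        theta = ft$par[["theta"]], c3 = ft$par[["c3"]],
        objective = ft$objective, converged = ft$converged))
    }
  }

  structure(list(
    cell_line = cell_line,
    stage1 = if (has_s1) list(rho = stage1$par[["rho"]],
                              K = stage1$par[["K"]],
                              objective = stage1$objective,
                              converged = stage1$converged) else NULL,
    stage2 = stage2, stage3 = stage3, stage4 = stage4,
    skipped = skipped, seed = seed, bounds = bounds, sigma = sigma
  ), class = "carrgo_fit")
}

#' @export
print.carrgo_fit <- function(x, ...) {
  cat("<carrgo_fit> cell line:", x$cell_line, " (seed", x$seed, ")\n")
  if (!is.null(x$stage1)) {
    cat(sprintf("  stage 1: rho = %.4g /day, K = %.4g CI (obj %.3g)\n",
                x$stage1$rho, x$stage1$K, x$stage1$objective))
  }
  cat(sprintf("  stage 2: %d Dex level(s); stage 3: %d E:T fit(s); stage 4: %d condition fit(s)\n",
              nrow(x$stage2), nrow(x$stage3), nrow(x$stage4)))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "),
                             "\n")
  invisible(x)
}

#' Tidy a staged fit into one row per estimated term
#'
#' @param x A `carrgo_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `et_ratio`, `dex0_ugml`, `term`,
#'   `estimate`.
#' @export
tidy.carrgo_fit <- function(x, ...) {
  out <- list()
  if (!is.null(x$stage1)) {
    out$s1 <- tibble(stage = 1L, et_ratio = NA_character_,
                     dex0_ugml = 0, term = c("rho", "K"),
                     estimate = c(x$stage1$rho, x$stage1$K))
  }
  if (nrow(x$stage2)) {
    out$s2 <- x$stage2 |>
      dplyr::transmute(stage = 2L, et_ratio = NA_character_,
                       dex0_ugml = .data$dex0_ugml, term = "c0",
                       estimate = .data$c0)
  }
  if (nrow(x$stage3)) {
    out$s3 <- x$stage3 |>
      tidyr::pivot_longer(c("kappa1", "kappa2", "theta"),
                          names_to = "term", values_to = "estimate") |>
      dplyr::transmute(stage = 3L, et_ratio = .data$et_ratio, dex0_ugml = 0,
                       term = .data$term, estimate = .data$estimate)
  }
  if (nrow(x$stage4)) {
    out$s4 <- x$stage4 |>
      tidyr::pivot_longer(c("kappa1", "kappa2", "theta", "c3"),
                          names_to = "term", values_to = "estimate") |>
      dplyr::transmute(stage = 4L, et_ratio = .data$et_ratio,
                       dex0_ugml = .data$dex0_ugml,
                       term = .data$term, estimate = .data$estimate)
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a staged fit
#'
#' @param x A `carrgo_fit` object.
#' @param ... Unused.
#' @return A tibble with the cell line, per-stage condition counts, total
#'   objective, convergence flag, and seed.
#' @export
glance.carrgo_fit <- function(x, ...) {
  objs <- c(if (!is.null(x$stage1)) x$stage1$objective,
            x$stage2$objective, x$stage3$objective, x$stage4$objective)
  conv <- c(if (!is.null(x$stage1)) x$stage1$converged,
            x$stage2$converged, x$stage3$converged, x$stage4$converged)
  tibble(
    cell_line = x$cell_line,
    n_stage2 = nrow(x$stage2), n_stage3 = nrow(x$stage3),
    n_stage4 = nrow(x$stage4),
    total_objective = sum(objs),
    all_converged = all(conv),
    n_skipped = length(x$skipped),
    seed = x$seed
  )
}

#' Reassemble full parameter sets for each fitted CAR-T condition
#'
#' Combines the staged estimates into one [carrgo_params()] per fitted
#' condition with CAR T-cells (stage 3 rows have `dex0_ugml = 0` and
#' `c0 = c3 = 0`).
#'
#' @param fit A `carrgo_fit` object.
#' @return A tibble with condition metadata and a list-column `params`.
#' @export
fitted_condition_params <- function(fit) {
  stopifnot(inherits(fit, "carrgo_fit"))
  if (is.null(fit$stage1)) stop("fit has no stage-1 estimates", call. = FALSE)
  rows <- list()
  mk <- function(kappa1, kappa2, theta, c0, c3, D0) {
    carrgo_params(rho = fit$stage1$rho, K = fit$stage1$K,
                  kappa1 = kappa1, kappa2 = kappa2, theta = theta,
                  c0 = c0, c3 = c3, sigma = fit$sigma, D0 = D0)
  }
  if (nrow(fit$stage3)) {
    rows$s3 <- fit$stage3 |>
      dplyr::mutate(dex0_ugml = 0, params = purrr::pmap(
        list(.data$kappa1, .data$kappa2, .data$theta),
        function(k1, k2, th) mk(k1, k2, th, 0, 0, 0))) |>
      dplyr::select("et_ratio", "dex0_ugml", "params")
  }
  if (nrow(fit$stage4)) {
    c0_for <- function(d0) {
      r <- fit$stage2[fit$stage2$dex0_ugml == d0, ]
      if (nrow(r)) r$c0[1] else 0
    }
    rows$s4 <- fit$stage4 |>
      dplyr::mutate(params = purrr::pmap(
        list(.data$kappa1, .data$kappa2, .data$theta, .data$c3,
             .data$dex0_ugml),
        function(k1, k2, th, c3, d0) mk(k1, k2, th, c0_for(d0), c3, d0))) |>
      dplyr::select("et_ratio", "dex0_ugml", "params")
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(cell_line = fit$cell_line, .before = 1)
}
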