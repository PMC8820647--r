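#' Particle swarm optimization (global-best PSO)
#'
#' Minimises `fn` over a box. Standard constricted global-best PSO with
#' inertia 0.729 and cognitive/social accelerations 1.49 (the conventional
#' Clerc-Kennedy constriction values); velocities are clamped to the box
#' width and positions clipped to the bounds. Used to obtain rough parameter
#' estimates that are then polished by Levenberg-Marquardt.
#'
#' @param fn Objective, `function(x) -> scalar`; non-finite values are
#'   treated as a large penalty so the swarm can continue past failed
#'   evaluations.
#' @param lower,upper Numeric bounds (finite, equal length).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param n_particles Swarm size.
#' @param iters Number of iterations.
#' @param inertia,c_cog,c_soc Velocity update coefficients.
#' @return A list with `par` (best position), `value` (best objective),
#'   `iters`, `n_evals`, `trace` (best value per iteration), and the final
#'   personal bests `pbest` / `pbest_val` (useful as multi-start points for
#'   local refinement).
#' @examples
#' pso_search(function(x) (x - 3)^2, lower = 0, upper = 10, seed = 1)$par
#' @export
pso_search <- function(fn, lower, upper, seed,
                       n_particles = 50, iters = 200,
                       inertia = 0.729, c_cog = 1.49, c_soc = 1.49) {
  stopifnot(is.function(fn), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper), length(lower) >= 1L)
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  set.seed(seed)
  d <- length(lower)
  width <- upper - lower
  eval_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  pos <- matrix(stats::runif(n_particles * d, lower, upper),
                nrow = n_particles, byrow = TRUE)
  vel <- matrix(stats::runif(n_particles * d, -width, width),
                nrow = n_particles, byrow = TRUE) * 0.1
  pbest <- pos
  pbest_val <- apply(pos, 1, eval_fn)
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]
  gbest_val <- pbest_val[g]
  trace <- numeric(iters)

  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(n_particles * d), nrow = n_particles)
    r2 <- matrix(stats::runif(n_particles * d), nrow = n_particles)
    vel <- inertia * vel +
      c_cog * r1 * (pbest - pos) +
      c_soc * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, matrix(-width, n_particles, d, byrow = TRUE)),
                matrix(width, n_particles, d, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lower, n_particles, d, byrow = TRUE)),
                matrix(upper, n_particles, d, byrow = TRUE))
    val <- apply(pos, 1, eval_fn)
    improved <- val < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]
      gbest_val <- pbest_val[g]
    }
    trace[it] <- gbest_val
  }
  ord <- order(pbest_val)
  list(par = as.numeric(gbest), value = gbest_val, iters = iters,
       n_evals = n_particles * (iters + 1), trace = trace,
       pbest = pbest[ord, , drop = FALSE], pbest_val = pbest_val[ord])
}
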