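# Random parameter draws within the observed assay ranges, used by the
# property-style tests. Draws are reproducible via the caller's seed.
rand_params <- function(n, with_dex = FALSE) {
  lapply(seq_len(n), function(i) {
    carrgo_params(
      rho = runif(1, 0.5, 12),
      K = runif(1, 1, 20),
      kappa1 = runif(1, 0.8, 90),
      kappa2 = runif(1, 0.1, 2),
      theta = runif(1, 0.01, 3),
      c0 = if (with_dex) runif(1, -10, 4) else 0,
      c3 = if (with_dex) runif(1, -11, 11) else 0,
      sigma = 5,
      D0 = if (with_dex) 10^runif(1, -4, 0) else 0
    )
  })
}

# generating truth used across recovery tests (the success regime of the
# default condition map)
truth_success <- function(d0 = 0) default_truth("SYN-GBM-1", "1:4", d0)
truth_failure <- function(d0 = 0.1) default_truth("SYN-GBM-1", "1:4", d0)

# small noise-free dataset covering all four staged-fit condition types
small_staged_dataset <- function(seed = 7, dex = 1e-3, duration_hr = 144) {
  generate_assay(
    assay_design(et_ratios = "1:4", dex_ugml = c(0, dex),
                 duration_hr = duration_hr),
    noise = noise_model("none"), seed = seed
  )
}

fast_control <- function(n_particles = 20, iters = 30, ...) {
  fit_control(n_particles = n_particles, iters = iters, ...)
}

# the default CAR-T weight (n_tumor / n_cart), reproduced independently
cond_weights_for_test <- function(cond) nrow(cond$tumor) / nrow(cond$cart)
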