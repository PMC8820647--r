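#' Experimental design of a synthetic cell-killing assay
#'
#' Describes the impedance-assay design grid that the generator emulates:
#' tumor cells seeded at 10K-20K cells per well (1-2 CI), grown for a 24 h
#' lead time, then treated simultaneously with CAR T-cells (E:T ratios 1:4,
#' 1:8, 1:20) and/or dexamethasone (0, 1e-4, 1e-3, 1e-2, 1e-1, 1 ug/ml),
#' with the tumor impedance sampled every 15 minutes for 144 h and CAR
#' T-cells (non-adherent) measured only at the initial and final times, all
#' in duplicate.
#'
#' @param cell_lines Character labels (default one synthetic line).
#' @param ci_seed_range Initial tumor seeding range, CI (1 CI ~ 10,000
#'   cells).
#' @param et_ratios Character E:T ratios `"1:n"`.
#' @param dex_ugml Initial Dex concentrations, ug/ml (include 0 for
#'   controls).
#' @param interval_hr Sampling interval, hours.
#' @param duration_hr Post-treatment follow-up, hours (assay runs 144-192 h).
#' @param replicates Wells per condition.
#' @param lead_hr Tumor-only growth before treatment, hours.
#' @return A list of class `assay_design`.
#' @export
assay_design <- function(cell_lines = "SYN-GBM-1",
                         ci_seed_range = c(1, 2),
                         et_ratios = c("1:4", "1:8", "1:20"),
                         dex_ugml = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                         interval_hr = 0.25,
                         duration_hr = 144,
                         replicates = 2,
                         lead_hr = 24) {
  stopifnot(length(cell_lines) >= 1, length(ci_seed_range) == 2,
            ci_seed_range[1] > 0, diff(ci_seed_range) >= 0,
            interval_hr > 0, duration_hr > 0, replicates >= 1,
            lead_hr >= 0, all(dex_ugml >= 0), length(dex_ugml) >= 1)
  if (any(is.na(et_ratios)) ||
      !all(grepl("^1:[0-9]+$", et_ratios))) {
    stop("`et_ratios` must look like \"1:4\"", call. = FALSE)
  }
  structure(list(cell_lines = cell_lines, ci_seed_range = ci_seed_range,
                 et_ratios = et_ratios, dex_ugml = dex_ugml,
                 interval_hr = interval_hr, duration_hr = duration_hr,
                 replicates = replicates, lead_hr = lead_hr),
            class = "assay_design")
}

et_fraction <- function(et_ratio) {
  1 / as.numeric(sub("^1:", "", et_ratio))
}

#' Measurement noise model for synthetic impedance data
#'
#' Default is multiplicative lognormal noise: the cell index is a positive,
#' signal-proportional impedance readout, so errors scale with the signal.
#' The lognormal sdlog is chosen so the coefficient of variation is exactly
#' `cv`. `additive_gaussian` adds noise with absolute standard deviation
#' `cv` (in CI). Values are floored at `floor` CI after noising.
#'
#' @param type One of `"multiplicative_lognormal"`, `"additive_gaussian"`,
#'   `"none"`.
#' @param cv Coefficient of variation (multiplicative) or absolute sd in CI
#'   (additive).
#' @param floor Measurement floor, CI.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(type = c("multiplicative_lognormal",
                                 "additive_gaussian", "none"),
                        cv = 0.05, floor = 0) {
  type <- match.arg(type)
  stopifnot(cv >= 0, floor >= 0)
  structure(list(type = type, cv = cv, floor = floor),
            class = "noise_model")
}

apply_noise <- function(ci, noise) {
  out <- switch(noise$type,
    none = ci,
    multiplicative_lognormal = {
      if (noise$cv == 0) ci else {
        sdlog <- sqrt(log(1 + noise$cv^2))
        ci * stats::rlnorm(length(ci), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
    },
    additive_gaussian = ci + stats::rnorm(length(ci), 0, noise$cv)
  )
  pmax(out, noise$floor)
}

#' Default generating parameters per condition
#'
#' The condition-to-truth map used by [generate_assay()] unless overridden.
#' Two regimes emulate the observed dose response: below 0.1 ug/ml of Dex,
#' CAR T-cell treatment succeeds (`theta/kappa2 = 0.25` CI, Dex raises CAR
#' T-cell turnover, `c3 > 0`); at 0.1 ug/ml and above it fails through
#' exhaustion (`kappa2` reduced, `theta` raised so `theta/kappa2 = 0.75`
#' CI, and `c3 = -2.4 < -theta`, so the coexistence equilibrium is
#' destabilised until about two Dex half-lives have elapsed). Tumor growth
#' (`rho = 1`/day, `K = 5` CI) and the mild pro-tumor Dex effect
#' (`c0 = -0.5`/day) are shared. Dex-free conditions have `c0 = c3 = 0`.
#'
#' @param cell_line,et_ratio,dex0_ugml Condition labels (`et_ratio` may be
#'   `NA` for tumor-only wells).
#' @return A [carrgo_params()] object with `D0 = dex0_ugml`.
#' @export
default_truth <- function(cell_line, et_ratio, dex0_ugml) {
  has_dex <- dex0_ugml > 0
  failure <- dex0_ugml >= 0.1
  carrgo_params(
    rho = 1.0, K = 5,
    kappa1 = 2.0,
    kappa2 = if (failure) 0.8 else 1.0,
    theta = if (failure) 0.6 else 0.25,
    c0 = if (has_dex) -0.5 else 0,
    c3 = if (!has_dex) 0 else if (failure) -2.4 else 0.3,
    sigma = 5, D0 = dex0_ugml
  )
}

#' Generate a synthetic cell-killing-assay dataset
#'
#' Simulates every condition of the design grid: tumor-only wells at each
#' Dex level plus every E:T x Dex combination, in replicate. Each cell line
#' draws one seeding density from the design range; tumor cells grow
#' drug-free and predator-free for the lead time; at treatment time (t = 0
#' of the output) CAR T-cells are added at `x0 * E:T` and Dex at its
#' initial concentration. The tumor series is sampled at the design
#' interval; CAR T-cells are recorded only at the initial and final times.
#' Noise is applied independently per replicate and observation.
#'
#' @param design An [assay_design()].
#' @param truth A function `(cell_line, et_ratio, dex0_ugml) ->`
#'   [carrgo_params()] giving the generating parameters per condition
#'   (default [default_truth()]). Its `rho`/`K` at `dex0 = 0` also drive
#'   the pre-treatment growth.
#' @param noise A [noise_model()].
#' @param seed Integer seed (required).
#' @return A list with `data` (long assay tibble, see [validate_assay()])
#'   and `truth` (tibble of conditions with a `params` list-column), for
#'   parameter-recovery studies.
#' @examples
#' out <- generate_assay(assay_design(dex_ugml = c(0, 0.1), et_ratios = "1:4",
#'                                    duration_hr = 48),
#'                       seed = 1)
#' dplyr::count(out$data, et_ratio, dex0_ugml, species)
#' @export
generate_assay <- function(design = assay_design(), truth = default_truth,
                           noise = noise_model(), seed) {
  stopifnot(inherits(design, "assay_design"), is.function(truth),
            inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  t_grid <- seq(0, design$duration_hr, by = design$interval_hr)
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(cell_line = design$cell_lines,
                       et_ratio = NA_character_,
                       dex0_ugml = design$dex_ugml),
    tidyr::expand_grid(cell_line = design$cell_lines,
                       et_ratio = design$et_ratios,
                       dex0_ugml = design$dex_ugml)
  )
  seeding <- setNames(stats::runif(length(design$cell_lines),
                                   design$ci_seed_range[1],
                                   design$ci_seed_range[2]),
                      design$cell_lines)

  rows <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cl <- grid$cell_line[i]; et <- grid$et_ratio[i]; d0 <- grid$dex0_ugml[i]
    pars <- truth(cl, et, d0)
    if (!inherits(pars, "carrgo_params") || pars$D0 != d0) {
      stop("`truth` must return carrgo_params with D0 equal to the ",
           "condition's Dex concentration", call. = FALSE)
    }
    # drug- and predator-free growth over the lead time
    p_lead <- truth(cl, NA_character_, 0)
    x0 <- if (design$lead_hr > 0) {
      lead <- carrgo_simulate(p_lead, x0 = seeding[[cl]], y0 = 0,
                              times = c(0, design$lead_hr), unit = "hours")
      lead$x_ci[2]
    } else seeding[[cl]]
    y0 <- if (is.na(et)) 0 else x0 * et_fraction(et)
    sim <- carrgo_simulate(pars, x0 = x0, y0 = y0, times = t_grid,
                           unit = "hours")
    t_cart <- range(t_grid)
    y_cart <- sim$y_ci[match(t_cart, sim$time_hr)]

    reps <- vector("list", design$replicates)
    for (r in seq_len(design$replicates)) {
      tumor <- tibble(cell_line = cl, et_ratio = et, dex0_ugml = d0,
                      well_id = sprintf("w%02d_r%d", i, r),
                      species = "tumor", time_hr = t_grid,
                      cell_index = apply_noise(sim$x_ci, noise))
      cart <- if (!is.na(et)) {
        tibble(cell_line = cl, et_ratio = et, dex0_ugml = d0,
               well_id = sprintf("w%02d_r%d", i, r),
               species = "cart", time_hr = t_cart,
               cell_index = apply_noise(y_cart, noise))
      } else NULL
      reps[[r]] <- dplyr::bind_rows(tumor, cart)
    }
    rows[[i]] <- dplyr::bind_rows(reps)
    truth_rows[[i]] <- tibble(cell_line = cl, et_ratio = et, dex0_ugml = d0,
                              x0 = x0, y0 = y0, params = list(pars))
  }
  list(data = validate_assay(dplyr::bind_rows(rows)),
       truth = dplyr::bind_rows(truth_rows))
}
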