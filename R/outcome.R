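#' Predicted post-clearance tumor equilibrium
#'
#' The tumor coordinate of the coexistence equilibrium after the drug has
#' cleared, \eqn{\theta/\kappa_2} (in CI): the single quantity that
#' determines the predicted final tumor burden. Near-zero values mean CAR
#' T-cell proliferation outpaces death and the coexistence equilibrium sits
#' at (almost) zero tumor cells, i.e. tumor eradication.
#'
#' @param params A [carrgo_params()] object with `kappa2 > 0`.
#' @return `theta / kappa2`, CI.
#' @examples
#' equilibrium_ratio(carrgo_params(1, 5, 2, 1, theta = 0.4))  # 0.4
#' @export
equilibrium_ratio <- function(params) {
  stopifnot(inherits(params, "carrgo_params"))
  if (params$kappa2 <= 0) stop("`kappa2` must be > 0", call. = FALSE)
  params$theta / params$kappa2
}

#' Classify predicted treatment outcome from the equilibrium ratio
#'
#' `"death"` when `ratio < threshold` (tumor eradication after transient
#' pseudo-progression), `"progression"` when `ratio > threshold`; a ratio
#' exactly at the threshold is flagged `"indeterminate"`.
#'
#' @param ratio Predicted equilibrium tumor burden(s) `theta/kappa2`, CI
#'   (>= 0).
#' @param threshold Decision threshold, CI (default 0.4, the empirically
#'   observed separation).
#' @return Character vector of outcome labels.
#' @export
classify_outcome <- function(ratio, threshold = 0.4) {
  stopifnot(all(ratio >= 0), length(threshold) == 1L, threshold >= 0)
  dplyr::case_when(
    ratio < threshold ~ "death",
    ratio > threshold ~ "progression",
    TRUE ~ "indeterminate"
  )
}

#' Estimate the success/failure threshold from observed outcomes
#'
#' Given per-condition equilibrium ratios and observed outcomes, returns
#' the separating threshold. If the two outcome groups are perfectly
#' separable the midpoint of the separating gap is returned with
#' `separable = TRUE`; otherwise an exhaustive scan over candidate
#' cut-points (midpoints between consecutive sorted ratios) picks the
#' threshold minimising misclassifications, ties resolved toward the lower
#' threshold, with `separable = FALSE`.
#'
#' @param records A data frame with numeric column `ratio` and column
#'   `observed` with values `"death"` / `"progression"`; both outcome
#'   classes must be present.
#' @return A list with `threshold` (CI), `separable`, `n_misclassified`.
#' @examples
#' rec <- tibble::tibble(ratio = c(0.1, 0.2, 0.6, 0.9),
#'                       observed = c("death", "death",
#'                                    "progression", "progression"))
#' estimate_threshold(rec)  # midpoint 0.4, separable
#' @export
estimate_threshold <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("ratio", "observed") %in% names(records)))
  if (!all(records$observed %in% c("death", "progression"))) {
    stop("`observed` must be \"death\" or \"progression\"", call. = FALSE)
  }
  rd <- records$ratio[records$observed == "death"]
  rp <- records$ratio[records$observed == "progression"]
  if (length(rd) == 0 || length(rp) == 0) {
    stop("need at least one record of each observed outcome", call. = FALSE)
  }
  if (max(rd) < min(rp)) {
    return(list(threshold = (max(rd) + min(rp)) / 2, separable = TRUE,
                n_misclassified = 0L))
  }
  r_sorted <- sort(unique(records$ratio))
  cuts <- c(r_sorted[1] / 2,
            (r_sorted[-1] + r_sorted[-length(r_sorted)]) / 2,
            r_sorted[length(r_sorted)] * 1.5)
  err <- vapply(cuts, function(ct) {
    sum(rd >= ct) + sum(rp <= ct)
  }, integer(1))
  best <- cuts[which.min(err)]  # which.min takes the first, i.e. lowest cut
  list(threshold = best, separable = FALSE,
       n_misclassified = min(err))
}

#' Per-condition outcome records from staged fits
#'
#' Combines fitted condition parameters with the measured (or simulated)
#' tumor series to produce one record per CAR-T condition: the post-
#' clearance equilibrium ratio `theta/kappa2`, the outcome observed in the
#' tumor trajectory (sustained drop below `extinction_eps`), and the
#' predicted outcome at `threshold`.
#'
#' @param fit A `carrgo_fit` from [staged_fit()].
#' @param data The long assay tibble the fit was run on (used for the
#'   observed outcome via [detect_outcome()] on the duplicate-averaged
#'   tumor series).
#' @param threshold Decision threshold, CI.
#' @param extinction_eps Extinction threshold for the observed outcome, CI.
#' @return A tibble with condition metadata, `ratio`, `observed`,
#'   `predicted`, `threshold`.
#' @export
outcome_records <- function(fit, data, threshold = 0.4,
                            extinction_eps = 0.01) {
  fp <- fitted_condition_params(fit)
  data <- validate_assay(data)
  obs <- purrr::pmap_chr(
    fp[, c("cell_line", "et_ratio", "dex0_ugml")],
    function(cell_line, et_ratio, dex0_ugml) {
      cond <- condition_data(data, cell_line, et_ratio, dex0_ugml)
      out <- detect_outcome(
        tibble(time_hr = cond$tumor$time_hr, x_ci = cond$tumor$ci),
        extinction_eps = extinction_eps)
      if (out$outcome == "tumor_death") "death" else "progression"
    })
  fp |>
    dplyr::mutate(
      ratio = purrr::map_dbl(.data$params, equilibrium_ratio),
      observed = obs,
      predicted = classify_outcome(.data$ratio, threshold),
      threshold = threshold
    ) |>
    dplyr::select(-"params")
}
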