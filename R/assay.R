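# Long-format cell-killing-assay schema shared by the synthetic generator,
# the fitting machinery and the CSV round trip:
#   cell_line, et_ratio ("1:4" etc., NA for tumor-only wells), dex0_ugml,
#   well_id, species ("tumor" or "cart"), time_hr, cell_index
# Tumor wells carry a dense impedance series (one point per sampling
# interval); CAR T-cells are non-adherent, so wells with CAR T-cells carry
# exactly two "cart" rows: the initial and final measurements.

assay_cols <- c("cell_line", "et_ratio", "dex0_ugml", "well_id",
                "species", "time_hr", "cell_index")

#' Validate a long-format assay table
#'
#' Checks the column set, species labels, non-negativity of cell index and
#' Dex concentration, and within-well monotone time stamps. Offending rows
#' are named by their (1-based) row number in the table.
#'
#' @param data A data frame in the long assay format.
#' @return The data as a tibble, invisibly usable downstream; errors
#'   otherwise.
#' @export
validate_assay <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(assay_cols, names(data))
  if (length(missing_cols)) {
    stop("missing assay column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as_tibble(data)
  if (nrow(data) == 0) return(data)
  bad <- which(!data$species %in% c("tumor", "cart"))
  if (length(bad)) {
    stop("invalid species label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(data$cell_index) | data$cell_index < 0)
  if (length(bad)) {
    stop("negative or non-finite cell_index at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(data$dex0_ugml) | data$dex0_ugml < 0)
  if (length(bad)) {
    stop("negative or non-finite dex0_ugml at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ok_time <- data |>
    dplyr::group_by(.data$cell_line, .data$et_ratio, .data$dex0_ugml,
                    .data$well_id, .data$species) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_hr, strictly = TRUE),
                     .groups = "drop")
  if (!all(ok_time$ok)) {
    stop("time_hr must be strictly increasing within each well/species",
         call. = FALSE)
  }
  data
}

#' Read / write assay tables (CSV round trip)
#'
#' Lossless CSV serialisation of the long assay format; reading validates
#' and reports offending rows.
#'
#' @param path File path.
#' @return `read_assay()`: a validated tibble. `write_assay()`: `path`,
#'   invisibly.
#' @export
read_assay <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    cell_line = readr::col_character(),
    et_ratio = readr::col_character(),
    dex0_ugml = readr::col_double(),
    well_id = readr::col_character(),
    species = readr::col_character(),
    time_hr = readr::col_double(),
    cell_index = readr::col_double()
  ))
  validate_assay(data)
}

#' @rdname read_assay
#' @param data A validated assay tibble.
#' @export
write_assay <- function(data, path) {
  data <- validate_assay(data)
  readr::write_csv(data[, assay_cols], path)
  invisible(path)
}

#' Enumerate experimental conditions present in an assay table
#'
#' @param data A long-format assay tibble.
#' @return A tibble with one row per (cell_line, et_ratio, dex0_ugml)
#'   condition, replicate counts, and `has_cart` / `has_dex` flags.
#' @export
conditions <- function(data) {
  data <- validate_assay(data)
  data |>
    dplyr::group_by(.data$cell_line, .data$et_ratio, .data$dex0_ugml) |>
    dplyr::summarise(
      n_wells = dplyr::n_distinct(.data$well_id),
      has_cart = any(.data$species == "cart"),
      has_dex = .data$dex0_ugml[1] > 0,
      .groups = "drop"
    )
}

#' Extract one condition, duplicates averaged, as a fitting unit
#'
#' Averages replicate wells point-wise (the fitting convention for this
#' assay design), and splits the tumor impedance series from the two CAR
#' T-cell endpoint measurements.
#'
#' @param data A long-format assay tibble.
#' @param cell_line,et_ratio,dex0_ugml Condition selectors; `et_ratio = NA`
#'   selects tumor-only wells.
#' @return A list of class `assay_condition` with elements `cell_line`,
#'   `et_ratio`, `dex0_ugml`, `has_cart`, `has_dex`, `tumor` (tibble
#'   `time_hr`, `ci`), `cart` (tibble `time_hr`, `ci`; zero rows when no CAR
#'   T-cells), `x0`, `y0`.
#' @export
condition_data <- function(data, cell_line, et_ratio, dex0_ugml) {
  data <- validate_assay(data)
  sel <- data$cell_line == cell_line &
    (if (is.na(et_ratio)) is.na(data$et_ratio)
     else !is.na(data$et_ratio) & data$et_ratio == et_ratio) &
    data$dex0_ugml == dex0_ugml
  sub <- data[sel, ]
  if (nrow(sub) == 0) {
    stop(sprintf("no data for condition (%s, %s, %g ug/ml)",
                 cell_line, et_ratio, dex0_ugml), call. = FALSE)
  }
  avg <- function(sp) {
    sub |>
      dplyr::filter(.data$species == sp) |>
      dplyr::group_by(.data$time_hr) |>
      dplyr::summarise(ci = mean(.data$cell_index), .groups = "drop") |>
      dplyr::arrange(.data$time_hr)
  }
  tumor <- avg("tumor")
  cart <- avg("cart")
  if (nrow(tumor) == 0) stop("condition has no tumor series", call. = FALSE)
  structure(list(
    cell_line = cell_line, et_ratio = et_ratio, dex0_ugml = dex0_ugml,
    has_cart = nrow(cart) > 0, has_dex = dex0_ugml > 0,
    tumor = tumor, cart = cart,
    x0 = tumor$ci[1],
    y0 = if (nrow(cart) > 0) cart$ci[1] else 0
  ), class = "assay_condition")
}

#' Down-sample the tumor series of an assay table
#'
#' Keeps every `factor`-th tumor time point per well (first point always
#' kept); CAR T-cell endpoint rows are untouched. Used for plotting clarity,
#' mirroring the 1/10 down-sampling of the assay figures.
#'
#' @param data A long-format assay tibble.
#' @param factor Integer >= 1.
#' @return The thinned tibble.
#' @export
downsample_assay <- function(data, factor) {
  data <- validate_assay(data)
  stopifnot(length(factor) == 1L, factor >= 1, factor == as.integer(factor))
  if (factor == 1) return(data)
  data |>
    dplyr::group_by(.data$cell_line, .data$et_ratio, .data$dex0_ugml,
                    .data$well_id, .data$species) |>
    dplyr::filter(.data$species == "cart" |
                    (dplyr::row_number() - 1) %% factor == 0) |>
    dplyr::ungroup()
}
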