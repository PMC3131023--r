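#' Read and write the package's tabular interchange formats
#'
#' All tables are plain CSV, UTF-8, `.` decimal separator:
#' * catch table: `site_id,area_type,stand_age,sampling_year,species,count`
#' * mass table: `species,mass_mg`
#' * MIB series: `site_id,stand_age,mib_mg,n_individuals,reliable`
#' * model curve: `age_years,mib_model_mg,phase` (plus `extrapolated` for
#'   predictions)
#'
#' @param path File path.
#' @return The corresponding tibble (`read_*`); the input, invisibly
#'   (`write_*`).
#' @name succmib_io
NULL

#' @rdname succmib_io
#' @export
read_catch_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    area_type = readr::col_character(),
    stand_age = readr::col_double(),
    sampling_year = readr::col_integer(),
    species = readr::col_character(),
    count = readr::col_integer()
  ))
  validate_catches(out)
  out
}

#' @rdname succmib_io
#' @export
read_mass_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(),
    mass_mg = readr::col_double()
  ))
}

#' @rdname succmib_io
#' @param series A `mib_series`.
#' @export
write_mib_series <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  invisible(series)
}

#' @rdname succmib_io
#' @export
read_mib_series <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    stand_age = readr::col_double(),
    mib_mg = readr::col_double(),
    n_individuals = readr::col_integer(),
    reliable = readr::col_logical()
  ))
  new_mib_series(out)
}

#' @rdname succmib_io
#' @param curve A `succession_curve`.
#' @export
write_model_curve <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(curve)
}

#' @rdname succmib_io
#' @param fit A `succession_fit`.
#' @param area_type Optional label for the output row.
#' @export
write_fit_result <- function(fit, path, area_type = NULL) {
  row <- tibble::tibble(
    area_type = area_type %||% fit$area_type %||% NA_character_,
    initial = fit$params$initial,
    delay = fit$params$delay,
    rate = fit$params$rate,
    recovery = fit$params$recovery,
    rss = fit$rss,
    n_used = fit$n_used,
    flags = paste(fit$flags, collapse = ";")
  )
  readr::write_csv(row, path)
  invisible(fit)
}

#' @rdname succmib_io
#' @param catches A catch table.
#' @export
write_catch_table <- function(catches, path) {
  readr::write_csv(tibble::as_tibble(catches), path)
  invisible(catches)
}
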