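#' Validate a catch table against a mass table
#'
#' A catch table records pitfall-trap catches: one row per site, sampling
#' year and species, with the number of individuals caught. A mass table
#' maps each species to its mean individual body mass in mg.
#'
#' @param catches Data frame with at least columns `species` and `count`;
#'   full tables also carry `site_id`, `area_type`, `stand_age`,
#'   `sampling_year`.
#' @param masses Data frame with columns `species`, `mass_mg`.
#' @return Invisibly, `catches`. Errors describe the first problem found and
#'   name the offending species or rows.
#' @export
validate_catches <- function(catches, masses = NULL) {
  if (!is.data.frame(catches)) stop("`catches` must be a data frame", call. = FALSE)
  need <- c("species", "count")
  miss <- setdiff(need, names(catches))
  if (length(miss)) {
    stop("`catches` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(catches)) {
    if (any(is.na(catches$species) | !nzchar(as.character(catches$species)))) {
      stop("`catches` contains empty species identifiers", call. = FALSE)
    }
    bad <- which(!is.finite(catches$count) | catches$count < 0)
    if (length(bad)) {
      stop("negative or missing counts in `catches` (first at row ", bad[1], ")",
           call. = FALSE)
    }
    if ("stand_age" %in% names(catches) && any(catches$stand_age < 0)) {
      stop("`stand_age` must be non-negative", call. = FALSE)
    }
  }
  if (!is.null(masses)) {
    if (!all(c("species", "mass_mg") %in% names(masses))) {
      stop("`masses` must have columns species, mass_mg", call. = FALSE)
    }
    if (any(!is.finite(masses$mass_mg) | masses$mass_mg <= 0)) {
      stop("all `mass_mg` values must be strictly positive", call. = FALSE)
    }
    unknown <- setdiff(unique(catches$species), masses$species)
    if (length(unknown)) {
      rows <- which(catches$species %in% unknown)
      stop("species missing from mass table: ",
           paste(unknown, collapse = ", "),
           " (catch rows ", paste(head(rows, 5L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  invisible(catches)
}

#' Mean Individual Biomass of one sample
#'
#' MIB is the total biomass of all carabids in a sample divided by the
#' number of individuals caught, i.e. the count-weighted mean of the species
#' masses. It rises as large-bodied, late-successional species come to
#' dominate the community. Samples with fewer individuals than
#' `reliability_threshold` (default 25) are flagged unreliable because MIB
#' becomes inaccurate at low counts; empty samples yield a missing MIB
#' rather than zero, since the quantity is undefined there.
#'
#' @param catches Catch rows for a single site and sampling year (columns
#'   `species`, `count`; any grouping columns are ignored here).
#' @param masses Mass table (`species`, `mass_mg`).
#' @param reliability_threshold Minimum individuals for a reliable MIB.
#' @return A one-row tibble with `mib_mg`, `n_individuals`, `reliable`.
#' @examples
#' catches <- data.frame(species = c("A", "B"), count = c(20, 30))
#' masses <- data.frame(species = c("A", "B"), mass_mg = c(50, 300))
#' compute_mib(catches, masses) # 200 mg from 50 individuals
#' @export
compute_mib <- function(catches, masses, reliability_threshold = 25) {
  validate_catches(catches, masses)
  counts <- catches$count
  mass <- masses$mass_mg[match(catches$species, masses$species)]
  n <- sum(counts)
  mib <- if (n > 0) sum(counts * mass) / n else NA_real_
  tibble::tibble(
    mib_mg = mib,
    n_individuals = as.integer(round(n)),
    reliable = n >= reliability_threshold & n > 0
  )
}

#' Build a MIB chronosequence series from a catch table
#'
#' One MIB point is produced per site and sampling year. Each site is
#' sampled in consecutive years, so its three (or however many) samples sit
#' at consecutive stand ages: the age attributed to a point is the site's
#' base age (its `stand_age` in the site's first sampling year) plus the
#' offset of the sampling year from that first year.
#'
#' @param catches Full catch table restricted to one area type (columns
#'   `site_id`, `stand_age`, `sampling_year`, `species`, `count`, optionally
#'   `area_type`).
#' @param masses Mass table (`species`, `mass_mg`).
#' @param area_type Optional label; defaults to the table's single
#'   `area_type` value when present.
#' @inheritParams compute_mib
#' @return A tibble of class `mib_series`, sorted by `stand_age`, with
#'   columns `site_id`, `stand_age`, `mib_mg`, `n_individuals`, `reliable`
#'   and the area type attached as attribute `area_type`.
#' @export
build_mib_series <- function(catches, masses, area_type = NULL,
                             reliability_threshold = 25) {
  if (!is.data.frame(catches) || nrow(catches) == 0L) {
    stop("`catches` is empty: cannot build a MIB series", call. = FALSE)
  }
  need <- c("site_id", "stand_age", "sampling_year")
  miss <- setdiff(need, names(catches))
  if (length(miss)) {
    stop("`catches` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_catches(catches, masses)
  if ("area_type" %in% names(catches)) {
    types <- unique(catches$area_type)
    if (length(types) > 1L) {
      stop("`catches` spans several area types (",
           paste(types, collapse = ", "),
           "); build one series per area type", call. = FALSE)
    }
    area_type <- area_type %||% types
  }

  # per site: first sampling year and the stand age recorded for it
  base <- catches |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      .first_year = min(.data$sampling_year),
      .base_age = .data$stand_age[which.min(.data$sampling_year)][1],
      .groups = "drop"
    )

  out <- catches |>
    dplyr::left_join(base, by = "site_id") |>
    dplyr::group_by(.data$site_id, .data$sampling_year,
                    .data$.first_year, .data$.base_age) |>
    dplyr::group_modify(~ compute_mib(.x, masses, reliability_threshold)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      stand_age = .data$.base_age + (.data$sampling_year - .data$.first_year)
    ) |>
    dplyr::select("site_id", "stand_age", "mib_mg", "n_individuals", "reliable") |>
    dplyr::arrange(.data$stand_age, .data$site_id)

  new_mib_series(out, area_type)
}

#' Construct a MIB series from precomputed points
#'
#' Low-level constructor used when the per-point MIB values already exist
#' (e.g. read from file or simulated); [build_mib_series()] is the usual
#' entry point from raw catches.
#'
#' @param points Data frame with columns `site_id`, `stand_age`, `mib_mg`,
#'   `n_individuals`, `reliable`.
#' @param area_type Optional area-type label stored as an attribute.
#' @return A `mib_series` tibble.
#' @export
new_mib_series <- function(points, area_type = NULL) {
  stopifnot(all(c("site_id", "stand_age", "mib_mg", "n_individuals",
                  "reliable") %in% names(points)))
  out <- tibble::as_tibble(points)
  attr(out, "area_type") <- area_type
  class(out) <- unique(c("mib_series", class(out)))
  out
}

#' Spearman rank correlation between MIB and stand age
#'
#' Tests whether MIB increases with stand age along a chronosequence.
#' Ties are handled with average ranks. For `n <= 8` the two-sided p-value
#' is computed by exact permutation over all `n!` orderings of the ranks;
#' for larger samples the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param series A `mib_series` (or any data frame with `stand_age`,
#'   `mib_mg` and, if `include_unreliable = FALSE`, `reliable`).
#' @param include_unreliable Keep points flagged unreliable (< 25
#'   individuals)? Default `TRUE`, since such points are plotted but
#'   distrusted; set `FALSE` to exclude them.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @examples
#' s <- new_mib_series(tibble::tibble(
#'   site_id = letters[1:5], stand_age = 1:5,
#'   mib_mg = c(42, 55, 90, 160, 220),
#'   n_individuals = rep(30L, 5), reliable = TRUE))
#' spearman_mib_age(s)
#' @export
spearman_mib_age <- function(series, include_unreliable = TRUE) {
  df <- tibble::as_tibble(series)
  if (!all(c("stand_age", "mib_mg") %in% names(df))) {
    stop("`series` must have columns stand_age and mib_mg", call. = FALSE)
  }
  df <- df[!is.na(df$mib_mg), ]
  if (!include_unreliable) {
    if (!"reliable" %in% names(df)) {
      stop("`series` has no `reliable` column to filter on", call. = FALSE)
    }
    df <- df[df$reliable, ]
  }
  n <- nrow(df)
  if (n < 3L) {
    stop("need at least 3 points for a Spearman test (have ", n, ")",
         call. = FALSE)
  }
  x <- df$stand_age
  y <- df$mib_mg
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("zero variance in age or MIB: correlation undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# all n! permutations of 1:n as a matrix (rows); intended for n <= 8
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
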