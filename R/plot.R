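#' Plot a MIB chronosequence series
#'
#' Scatter of MIB against stand age; points computed from fewer than 25
#' individuals are drawn as open circles, the convention for marking
#' unreliable MIB values.
#'
#' @param object A `mib_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mib_series
#' @export
autoplot.mib_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$mib_mg), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stand_age, y = .data$mib_mg)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$reliable), size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "≥ 25 individuals", `FALSE` = "< 25 individuals"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "Age of stand (years)", y = "MIB (mg)",
      title = attr(object, "area_type") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a succession model curve
#'
#' Line plot of the modelled MIB trajectory over stand age. Segments listed
#' in `dashed_phases` (or, for predictions, extrapolated ages) are drawn
#' dashed, the convention for parts of the curve the data cannot verify.
#'
#' @param object A `succession_curve`.
#' @param dashed_phases Phases to style dashed (e.g. `c("increase",
#'   "stagnation")` when the rate and recovery level are unverified).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot succession_curve
#' @export
autoplot.succession_curve <- function(object, dashed_phases = character(), ...) {
  df <- tibble::as_tibble(object)
  df$verified <- !(df$phase %in% dashed_phases)
  if ("extrapolated" %in% names(df)) df$verified <- df$verified & !df$extrapolated
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years, y = .data$mib_model_mg)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$verified, group = 1)) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "supported", `FALSE` = "unverified"),
      name = NULL
    ) +
    ggplot2::labs(x = "Age of stand (years)", y = "MIB (mg)") +
    ggplot2::theme_minimal()
}

#' Overlay a fitted model curve on its MIB series
#'
#' @param object A `succession_fit`.
#' @param ages Age grid for the curve (default 0–60 years).
#' @param theta Stagnation threshold for phase labels.
#' @param ... Unused.
#' @return A ggplot with observed points (open circles when unreliable) and
#'   the fitted curve; regimes governed by flagged parameters are dashed.
#' @method autoplot succession_fit
#' @export
autoplot.succession_fit <- function(object, ages = 0:60, theta = 0.95, ...) {
  curve <- succession_curve(object$params, ages, theta = theta)
  dashed <- flagged_phases(object$flags)
  base <- autoplot.succession_curve(curve, dashed_phases = dashed)
  df <- object$data
  if (!"reliable" %in% names(df)) df$reliable <- TRUE
  base +
    ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$stand_age, y = .data$mib_mg,
                   shape = .data$reliable),
      size = 2.5, inherit.aes = FALSE
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "≥ 25 individuals", `FALSE` = "< 25 individuals"),
      name = NULL
    )
}

# map flagged parameters to the curve regimes they govern
flagged_phases <- function(flags) {
  phases <- character()
  if (any(c("initial", "delay") %in% flags)) phases <- c(phases, "delay")
  if ("rate" %in% flags) phases <- c(phases, "increase")
  if (any(c("rate", "recovery") %in% flags)) phases <- c(phases, "stagnation")
  unique(phases)
}
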