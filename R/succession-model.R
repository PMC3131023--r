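#' Four-parameter delayed logistic succession model
#'
#' Succession on a degraded area is summarised by a single state variable
#' (here the Mean Individual Biomass of carabids, in mg) that starts at an
#' *initial degradation level*, may sit there for a *delay* of some years,
#' then rises logistically at an *increase rate* towards an asymptotic
#' *recovery level*.
#'
#' @param initial Initial degradation level (mg MIB), strictly positive and
#'   below `recovery`.
#' @param delay Delay before the logistic rise starts (years), non-negative.
#'   May be fractional.
#' @param rate Increase rate of the logistic phase (1/years), non-negative.
#' @param recovery Recovery level (mg MIB), the asymptote; must exceed
#'   `initial`.
#'
#' @return An object of class `succession_params`: a named list with the four
#'   parameters.
#' @examples
#' p <- succession_params(initial = 40, delay = 10, rate = 0.6, recovery = 210)
#' succession_evaluate(p, age = c(5, 10, 30, 60))
#' @export
succession_params <- function(initial, delay, rate, recovery) {
  for (nm in c("initial", "delay", "rate", "recovery")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (initial <= 0) stop("`initial` must be > 0", call. = FALSE)
  if (recovery <= initial) {
    stop("`recovery` must exceed `initial` (got initial = ", initial,
         ", recovery = ", recovery, ")", call. = FALSE)
  }
  if (delay < 0) stop("`delay` must be >= 0", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  structure(
    list(initial = initial, delay = delay, rate = rate, recovery = recovery),
    class = "succession_params"
  )
}

#' @export
print.succession_params <- function(x, ...) {
  cat("Delayed logistic succession parameters\n")
  cat(sprintf("  initial degradation level: %g mg\n", x$initial))
  cat(sprintf("  delay:                     %g years\n", x$delay))
  cat(sprintf("  increase rate:             %g 1/years\n", x$rate))
  cat(sprintf("  recovery level:            %g mg\n", x$recovery))
  invisible(x)
}

as_succession_params <- function(x) {
  if (inherits(x, "succession_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    need <- c("initial", "delay", "rate", "recovery")
    if (all(need %in% names(x))) {
      return(succession_params(x$initial, x$delay, x$rate, x$recovery))
    }
  }
  stop("cannot interpret `params`: supply succession_params()", call. = FALSE)
}

#' Integration constant of the logistic solution
#'
#' The closed-form logistic solution can be written
#' `N(t) = c e^{rt} / (1 + c e^{rt} / K)` with
#' `c = N(0) / (1 - N(0)/K)`, where `N(0)` is the initial level and `K` the
#' recovery level. The constant is only defined for `0 < N(0) < K`.
#'
#' @param initial Initial level (mg), `0 < initial < recovery`.
#' @param recovery Recovery level (mg).
#' @return The constant `c` (mg); always exceeds `initial`.
#' @examples
#' logistic_c(40, 250) # 47.619...
#' @export
logistic_c <- function(initial, recovery) {
  if (!is.numeric(initial) || !is.numeric(recovery)) {
    stop("`initial` and `recovery` must be numeric", call. = FALSE)
  }
  if (any(initial <= 0)) stop("`initial` must be > 0", call. = FALSE)
  if (any(initial >= recovery)) {
    stop("`initial` must be strictly below `recovery`", call. = FALSE)
  }
  initial / (1 - initial / recovery)
}

#' Evaluate the delayed logistic model at given stand ages
#'
#' For stand age `a` the model time is `t = a - delay`. While `t < 0` the
#' state stays at the initial degradation level; for `t >= 0` it follows the
#' logistic solution. The implementation uses the numerically stable
#' rearrangement `K / (1 + ((K - N0)/N0) e^{-rt})` (a decaying exponential),
#' which is algebraically identical to the `c e^{rt}` form but cannot
#' overflow for large `rate * t`.
#'
#' @param params A [succession_params()] object (or coercible list).
#' @param age Stand age(s) in years, non-negative.
#' @return Numeric vector of model MIB values (mg), same length as `age`;
#'   each value lies in `[initial, recovery)`.
#' @examples
#' ash <- succession_params(40, 10, 0.28, 210)
#' succession_evaluate(ash, c(5, 9.9, 10, 20)) # flat at 40 through the delay
#' @export
succession_evaluate <- function(params, age) {
  params <- as_succession_params(params)
  if (!is.numeric(age)) stop("`age` must be numeric", call. = FALSE)
  if (any(age < 0, na.rm = TRUE)) {
    stop("`age` must be non-negative (stand ages)", call. = FALSE)
  }
  t <- age - params$delay
  n0 <- params$initial
  k <- params$recovery
  out <- k / (1 + ((k - n0) / n0) * exp(-params$rate * pmax(t, 0)))
  # both branches agree analytically at t = 0; assigning makes it bit-exact
  out[t <= 0] <- n0
  out
}

#' Logistic growth rate of the succession state
#'
#' Right-hand side of the logistic differential equation
#' `dN/dt = r N (K - N) / K` that the closed-form solution integrates.
#'
#' @param params A [succession_params()] object.
#' @param n Current state (mg MIB), `0 < n <= recovery`.
#' @return Growth rate `dN/dt` (mg/year); zero at `n = recovery`.
#' @export
succession_gradient <- function(params, n) {
  params <- as_succession_params(params)
  if (any(n <= 0) || any(n > params$recovery)) {
    stop("`n` must lie in (0, recovery]", call. = FALSE)
  }
  params$rate * n * (params$recovery - n) / params$recovery
}

#' Classify the succession phase at a stand age
#'
#' Three phases are distinguished: the *delay phase* (`age < delay`), the
#' *increase phase*, and the *stagnation phase* once the state has reached a
#' fraction `theta` of the recovery level. The delay/increase boundary is part
#' of the model; the increase/stagnation boundary is a reporting convention
#' (default `theta = 0.95`).
#'
#' @inheritParams succession_evaluate
#' @param theta Fraction of the recovery level above which the state counts
#'   as stagnating; default 0.95.
#' @return Character vector in `c("delay", "increase", "stagnation")`.
#' @export
classify_phase <- function(params, age, theta = 0.95) {
  params <- as_succession_params(params)
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, theta <= 1)
  n <- succession_evaluate(params, age)
  phase <- ifelse(age < params$delay, "delay",
                  ifelse(n >= theta * params$recovery, "stagnation", "increase"))
  phase
}

#' Tabulate a model curve over a grid of stand ages
#'
#' @inheritParams classify_phase
#' @param ages Numeric grid of stand ages (years); may be empty.
#' @return A tibble of class `succession_curve` with columns `age_years`,
#'   `mib_model_mg` and `phase`; the parameters are attached as attribute
#'   `params`.
#' @examples
#' succession_curve(succession_params(40, 0, 0.5, 250), ages = 0:60)
#' @export
succession_curve <- function(params, ages, theta = 0.95) {
  params <- as_succession_params(params)
  if (length(ages) == 0L) {
    out <- tibble::tibble(age_years = numeric(), mib_model_mg = numeric(),
                          phase = character())
  } else {
    out <- tibble::tibble(
      age_years = as.numeric(ages),
      mib_model_mg = succession_evaluate(params, ages),
      phase = classify_phase(params, ages, theta = theta)
    )
  }
  attr(out, "params") <- params
  class(out) <- c("succession_curve", class(out))
  out
}

#' Area-type parameter presets
#'
#' Parameter sets for the five degraded area types studied in the Polish
#' chronosequences: planted stands on forest soil, naturally regenerated and
#' planted stands on post-agricultural soil, and planted stands on a power
#' station ash heap and a brown coal mining heap. Values are read from the
#' shipped preset file (see [system.file()] `extdata/area_presets.yaml`).
#' Several entries could not be verified against field data (e.g. the ash
#' heap's increase rate is a theoretical value); these are listed per area in
#' the `unverified` column.
#'
#' @return A tibble with one row per area type: `area_type`, `initial`,
#'   `delay`, `rate`, `recovery`, and a list-column `unverified` naming the
#'   parameters that field data could not confirm.
#' @examples
#' succession_presets()
#' preset_params("mining_heap")
#' @export
succession_presets <- function() {
  path <- system.file("extdata", "area_presets.yaml", package = "succmib",
                      mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  purrr::map_dfr(names(cfg), function(area) {
    p <- cfg[[area]]
    tibble::tibble(
      area_type = area,
      initial = p$initial_level_mg,
      delay = p$delay_years,
      rate = p$increase_rate_per_year,
      recovery = p$recovery_level_mg,
      unverified = list(as.character(p$unverified %||% character()))
    )
  })
}

#' @rdname succession_presets
#' @param area_type One of the preset area-type labels.
#' @export
preset_params <- function(area_type) {
  presets <- succession_presets()
  row <- presets[presets$area_type == area_type, ]
  if (nrow(row) != 1L) {
    stop("unknown area type '", area_type, "'; available: ",
         paste(presets$area_type, collapse = ", "), call. = FALSE)
  }
  succession_params(row$initial, row$delay, row$rate, row$recovery)
}
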