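#' Fit the delayed logistic succession model to a MIB series
#'
#' Parameters are estimated by least squares on the observed MIB values.
#' Because the model is piecewise in the delay (non-smooth where the flat
#' delay phase meets the logistic rise), the delay is profiled over a grid of
#' candidate values; at each candidate the remaining free parameters are
#' estimated by bounded Levenberg--Marquardt least squares, and the candidate
#' with the smallest residual sum of squares wins. Any of the four parameters
#' can be fixed (e.g. `fix_initial = 40` to pin the initial degradation level
#' when young stands are missing).
#'
#' Identifiability of the parameters depends on the age span of the data,
#' and the fit flags parameters the series cannot constrain: when no points
#' lie at ages below `delay + 2` years the initial level and the delay are
#' flagged; when no point reaches 80% of the fitted recovery level, the
#' recovery level is flagged.
#'
#' @param series A `mib_series` (or data frame with `stand_age`, `mib_mg`,
#'   optionally `n_individuals` and `reliable`).
#' @param fix_initial,fix_delay,fix_rate,fix_recovery Optional fixed values;
#'   `NULL` (default) leaves the parameter free.
#' @param delay_grid Candidate delays in years (default 0 to 30 by 0.5);
#'   ignored when `fix_delay` is given.
#' @param exclude_unreliable Drop points flagged unreliable before fitting.
#' @param weight_by_n Weight squared residuals proportionally to
#'   `n_individuals` (MIB from larger catches is more precise).
#' @param rate_max Upper bound for the increase rate (1/years).
#' @param recovery_max Upper bound for the recovery level (mg); default
#'   `4 * max(mib)`.
#' @return An object of class `succession_fit`: parameters, residual sum of
#'   squares, number of points used, identifiability flags, the delay
#'   profile, and the data with fitted values. Use [tidy()], [glance()],
#'   [predict()] and [autoplot()] on it.
#' @examples
#' pars <- succession_params(40, 10, 0.6, 210)
#' series <- new_mib_series(tibble::tibble(
#'   site_id = "sim", stand_age = seq(0, 60, 2),
#'   mib_mg = succession_evaluate(pars, seq(0, 60, 2)),
#'   n_individuals = 100L, reliable = TRUE))
#' fit <- fit_succession(series)
#' tidy(fit)
#' @export
fit_succession <- function(series,
                           fix_initial = NULL, fix_delay = NULL,
                           fix_rate = NULL, fix_recovery = NULL,
                           delay_grid = seq(0, 30, by = 0.5),
                           exclude_unreliable = FALSE,
                           weight_by_n = FALSE,
                           rate_max = 5,
                           recovery_max = NULL) {
  df <- tibble::as_tibble(series)
  if (!all(c("stand_age", "mib_mg") %in% names(df))) {
    stop("`series` must have columns stand_age and mib_mg", call. = FALSE)
  }
  df <- df[!is.na(df$mib_mg), ]
  if (exclude_unreliable) {
    if (!"reliable" %in% names(df)) {
      stop("`series` has no `reliable` column to filter on", call. = FALSE)
    }
    df <- df[df$reliable, ]
  }
  n <- nrow(df)
  fixed <- list(initial = fix_initial, delay = fix_delay,
                rate = fix_rate, recovery = fix_recovery)
  free <- names(fixed)[vapply(fixed, is.null, logical(1))]
  k <- length(free)
  if (n < k + 1L) {
    stop("too few points: ", n, " observations cannot constrain ", k,
         " free parameter(s); need at least ", k + 1L, call. = FALSE)
  }
  if (length(unique(df$mib_mg)) < 2L && k > 0L) {
    stop("degenerate series: MIB is constant, the data carry no ",
         "information about the succession trajectory", call. = FALSE)
  }
  if (length(delay_grid) == 0L) stop("`delay_grid` is empty", call. = FALSE)

  ages <- df$stand_age
  obs <- df$mib_mg
  w <- if (weight_by_n) {
    if (!"n_individuals" %in% names(df)) {
      stop("`weight_by_n = TRUE` needs an `n_individuals` column", call. = FALSE)
    }
    sqrt(df$n_individuals / mean(df$n_individuals))
  } else {
    rep(1, n)
  }
  recovery_max <- recovery_max %||% (4 * max(obs))

  candidates <- if (is.null(fix_delay)) delay_grid else fix_delay
  profile <- purrr::map_dfr(candidates, function(d) {
    sol <- fit_at_delay(d, ages, obs, w, fixed, rate_max, recovery_max)
    tibble::tibble(delay = d, rss = sol$rss, params = list(sol$params))
  })
  best <- profile[which.min(profile$rss), ]
  params <- best$params[[1]]
  fitted <- succession_evaluate(params, ages)

  flags <- character()
  if (!any(ages < params$delay + 2)) flags <- c(flags, "initial", "delay")
  if (!any(fitted >= 0.8 * params$recovery)) flags <- c(flags, "recovery")
  flags <- setdiff(flags, names(fixed)[!vapply(fixed, is.null, logical(1))])

  structure(list(
    params = params,
    rss = best$rss,
    n_used = n,
    flags = flags,
    free = free,
    options = list(fixed = fixed, delay_grid = candidates,
                   exclude_unreliable = exclude_unreliable,
                   weight_by_n = weight_by_n,
                   rate_max = rate_max, recovery_max = recovery_max),
    delay_profile = profile[c("delay", "rss")],
    data = dplyr::mutate(df, fitted = fitted, residual = obs - fitted),
    area_type = attr(series, "area_type")
  ), class = "succession_fit")
}

# least squares over the continuous parameters at one fixed delay;
# parameterised as (initial, rate, span) with recovery = initial + span so
# initial < recovery holds structurally under box bounds
fit_at_delay <- function(delay, ages, obs, w, fixed, rate_max, recovery_max) {
  getp <- function(par) {
    initial <- fixed$initial %||% par[["initial"]]
    rate <- fixed$rate %||% par[["rate"]]
    recovery <- fixed$recovery %||% (initial + par[["span"]])
    list(initial = initial, delay = delay, rate = rate, recovery = recovery)
  }
  resid_fun <- function(par) {
    p <- getp(par)
    if (p$initial >= p$recovery) return(rep(1e6, length(obs)))
    w * (obs - succession_evaluate(
      succession_params(p$initial, p$delay, p$rate, p$recovery), ages))
  }

  start <- c()
  lower <- c()
  upper <- c()
  if (is.null(fixed$initial)) {
    start["initial"] <- max(min(obs), 1e-3)
    lower["initial"] <- 1e-6
    upper["initial"] <- if (is.null(fixed$recovery)) max(obs) else
      fixed$recovery - 1e-6
  }
  if (is.null(fixed$rate)) {
    start["rate"] <- 0.2
    lower["rate"] <- 0
    upper["rate"] <- rate_max
  }
  if (is.null(fixed$recovery)) {
    init0 <- fixed$initial %||% max(min(obs), 1e-3)
    start["span"] <- max(max(obs) - init0, 1)
    lower["span"] <- 1e-6
    upper["span"] <- recovery_max
  }

  if (length(start) == 0L) {
    p <- getp(numeric())
    rss <- sum((w * (obs - succession_evaluate(
      succession_params(p$initial, p$delay, p$rate, p$recovery), ages)))^2)
    return(list(
      params = succession_params(p$initial, p$delay, p$rate, p$recovery),
      rss = rss))
  }

  sol <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  p <- getp(sol$par)
  list(
    params = succession_params(p$initial, p$delay, p$rate, p$recovery),
    rss = sum(resid_fun(sol$par)^2)
  )
}

#' @export
print.succession_fit <- function(x, ...) {
  cat("Delayed logistic succession fit",
      if (!is.null(x$area_type)) paste0(" (", x$area_type, ")"), "\n", sep = "")
  print(x$params)
  cat(sprintf("  rss: %.6g mg^2 on %d points", x$rss, x$n_used))
  if (length(x$flags)) {
    cat("\n  unconstrained by data: ", paste(x$flags, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @method tidy succession_fit
#' @export
tidy.succession_fit <- function(x, ...) {
  fixed <- !vapply(x$options$fixed, is.null, logical(1))
  tibble::tibble(
    term = c("initial", "delay", "rate", "recovery"),
    estimate = c(x$params$initial, x$params$delay, x$params$rate,
                 x$params$recovery),
    fixed = unname(fixed[c("initial", "delay", "rate", "recovery")]),
    flagged = c("initial", "delay", "rate", "recovery") %in% x$flags
  )
}

#' @method glance succession_fit
#' @export
glance.succession_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss,
    sigma = sqrt(x$rss / max(x$n_used - length(x$free), 1L)),
    n_used = x$n_used,
    n_free = length(x$free),
    n_flagged = length(x$flags)
  )
}

#' Predict a model curve from a succession fit
#'
#' Evaluates the fitted curve over a grid of stand ages, labelling each
#' point's phase; ages beyond the observed maximum are flagged
#' `extrapolated`, since the data say nothing about the trajectory there.
#'
#' @param object A `succession_fit`.
#' @param ages Stand ages (years); defaults to 0 to 60.
#' @param theta Stagnation threshold passed to [classify_phase()].
#' @param ... Unused.
#' @return A `succession_curve` tibble with an extra `extrapolated` column.
#' @export
predict.succession_fit <- function(object, ages = 0:60, theta = 0.95, ...) {
  out <- succession_curve(object$params, ages, theta = theta)
  out$extrapolated <- if (nrow(out)) {
    out$age_years > max(object$data$stand_age)
  } else {
    logical()
  }
  out
}
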