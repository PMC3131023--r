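#' Two-guild carabid species pool
#'
#' The MIB rationale is a dominance shift: early-successional communities
#' are dominated by small-bodied carabids, late-successional ones by
#' large-bodied species. The simulator realises this with the minimal
#' mechanism consistent with that rationale — two guilds of species whose
#' masses are spread symmetrically around a small and a large guild mean, so
#' that the expected mass of an individual drawn with guild weight `w` is
#' exactly `w * mean_large + (1 - w) * mean_small`.
#'
#' @param n_small,n_large Number of species per guild.
#' @param mean_small,mean_large Guild mean masses (mg); defaults 40 and 450
#'   bracket all preset recovery levels (40–290 mg).
#' @param spread Relative half-width of the symmetric within-guild mass
#'   spread (default 0.2, i.e. masses evenly spaced over mean ± 20%).
#' @return A tibble of class `species_pool` with columns `species`, `guild`
#'   (`small_early` / `large_late`) and `mass_mg`.
#' @examples
#' species_pool()
#' @export
species_pool <- function(n_small = 6, n_large = 6,
                         mean_small = 40, mean_large = 450,
                         spread = 0.2) {
  stopifnot(n_small >= 1, n_large >= 1, mean_small > 0,
            mean_large > 0, spread >= 0, spread < 1)
  if (mean_small >= mean_large) {
    stop("`mean_small` must be below `mean_large`", call. = FALSE)
  }
  symmetric <- function(m, n) {
    if (n == 1L) return(m)
    m * (1 + spread * seq(-1, 1, length.out = n))
  }
  out <- tibble::tibble(
    species = c(sprintf("small_sp%02d", seq_len(n_small)),
                sprintf("large_sp%02d", seq_len(n_large))),
    guild = rep(c("small_early", "large_late"), c(n_small, n_large)),
    mass_mg = c(symmetric(mean_small, n_small),
                symmetric(mean_large, n_large))
  )
  class(out) <- unique(c("species_pool", class(out)))
  out
}

#' Mass table of a species pool
#'
#' @param pool A [species_pool()].
#' @return A tibble `species`, `mass_mg` usable wherever a mass table is
#'   expected.
#' @export
pool_mass_table <- function(pool) {
  tibble::as_tibble(pool)[c("species", "mass_mg")]
}

#' Large-guild weight reproducing a target MIB
#'
#' Solves `w * m_L + (1 - w) * m_S = N(age)` for the probability `w` that a
#' sampled individual belongs to the large-bodied guild, where `m_S`, `m_L`
#' are the guild mean masses and `N(age)` the model MIB at that stand age.
#' The solution is clamped to `[0, 1]`, so targets outside the guild-mean
#' bracket saturate at pure small or pure large communities.
#'
#' @param params A [succession_params()] object.
#' @param age Stand age(s) in years.
#' @param pool A [species_pool()].
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' solve_guild_weight(succession_params(40, 10, 0.6, 210), 25, species_pool())
#' @export
solve_guild_weight <- function(params, age, pool) {
  means <- tapply(pool$mass_mg, pool$guild, mean)
  m_s <- means[["small_early"]]
  m_l <- means[["large_late"]]
  if (!is.finite(m_s) || !is.finite(m_l) || m_s == m_l) {
    stop("degenerate pool: guild mean masses must differ", call. = FALSE)
  }
  target <- succession_evaluate(params, age)
  pmin(pmax((target - m_s) / (m_l - m_s), 0), 1)
}

#' Chronosequence sampling design for the simulator
#'
#' @param area_type Label for the simulated area type.
#' @param params [succession_params()] driving the expected MIB trajectory.
#' @param base_ages Stand ages (years) of the sites in the first sampling
#'   year.
#' @param n_years Number of consecutive sampling years per site (default 3).
#' @param first_year First calendar sampling year (default 2004).
#' @param catch_mean Expected individuals caught per site and year.
#' @param overdispersion Non-negative; 0 gives Poisson catch totals, larger
#'   values negative-binomial totals with variance
#'   `mu + overdispersion * mu^2` (pitfall catches are typically
#'   overdispersed).
#' @param seed Master seed; every site-year draws from its own
#'   deterministically derived stream, so extending a design does not change
#'   existing draws.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(area_type, params, base_ages, n_years = 3,
                       first_year = 2004, catch_mean = 200,
                       overdispersion = 0, seed = 1) {
  params <- as_succession_params(params)
  stopifnot(length(base_ages) >= 1, all(base_ages >= 0),
            n_years >= 1, catch_mean > 0, overdispersion >= 0)
  structure(list(
    area_type = area_type, params = params,
    base_ages = as.numeric(base_ages), n_years = as.integer(n_years),
    first_year = as.integer(first_year), catch_mean = catch_mean,
    overdispersion = overdispersion, seed = as.integer(seed)
  ), class = "sim_design")
}

# deterministic per-site-year substream seed below 2^31
substream_seed <- function(seed, site, year_offset) {
  (((seed %% 1000003L) * 10007L) + site * 131L + year_offset) %% 2147483647L
}

#' Simulate pitfall catches along a chronosequence
#'
#' For every site and sampling year the catch total is drawn from a Poisson
#' (or negative binomial when overdispersed) distribution; each individual
#' is assigned to the large-bodied guild with the weight from
#' [solve_guild_weight()] at the site's age in that year, then to a species
#' uniformly within its guild. The expected sample MIB therefore tracks
#' `succession_evaluate(params, age)` wherever the trajectory lies between
#' the guild means. Fully reproducible from the design's seed.
#'
#' @param design A [sim_design()].
#' @param pool A [species_pool()]; defaults to [species_pool()].
#' @return A catch table tibble (`site_id`, `area_type`, `stand_age`,
#'   `sampling_year`, `species`, `count`) valid as input to
#'   [build_mib_series()] with [pool_mass_table()] as the mass table.
#' @examples
#' d <- sim_design("mining_heap", preset_params("mining_heap"),
#'                 base_ages = c(3, 9, 16, 23), seed = 42)
#' catches <- simulate_chronosequence(d)
#' head(catches)
#' @export
simulate_chronosequence <- function(design, pool = species_pool()) {
  if (!inherits(design, "sim_design")) {
    stop("`design` must be a sim_design()", call. = FALSE)
  }
  small <- pool$species[pool$guild == "small_early"]
  large <- pool$species[pool$guild == "large_late"]
  if (length(small) == 0L || length(large) == 0L) {
    stop("pool must contain both guilds", call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    site = seq_along(design$base_ages),
    offset = seq_len(design$n_years) - 1L
  )
  rows <- purrr::pmap_dfr(grid, function(site, offset) {
    age <- design$base_ages[site] + offset
    w <- solve_guild_weight(design$params, age, pool)
    # local RNG stream; does not disturb the caller's RNG state
    seed <- substream_seed(design$seed, site, offset)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    total <- if (design$overdispersion == 0) {
      rpois(1L, design$catch_mean)
    } else {
      rnbinom(1L, mu = design$catch_mean, size = 1 / design$overdispersion)
    }
    if (total == 0L) {
      # zero-catch site-years still appear so MIB can flag them missing
      return(tibble::tibble(
        site_id = sprintf("%s_s%02d", design$area_type, site),
        area_type = design$area_type,
        stand_age = design$base_ages[site],
        sampling_year = design$first_year + offset,
        species = small[1], count = 0L
      ))
    }
    is_large <- runif(total) < w
    sp <- character(total)
    sp[is_large] <- sample(large, sum(is_large), replace = TRUE)
    sp[!is_large] <- sample(small, sum(!is_large), replace = TRUE)
    counts <- table(sp)
    tibble::tibble(
      site_id = sprintf("%s_s%02d", design$area_type, site),
      area_type = design$area_type,
      stand_age = design$base_ages[site],
      sampling_year = design$first_year + offset,
      species = names(counts),
      count = as.integer(counts)
    )
  })
  rows
}

#' Shipped chronosequence design presets
#'
#' One design per studied area type, mirroring the field sampling effort:
#' 14 forest-soil sites aged 21–119 years, 13 naturally regenerated
#' post-agricultural sites aged 0–64, 69 planted post-agricultural sites
#' aged 2–119, 3 ash-heap sites aged 8–14 and 4 mining-heap sites aged 3–23,
#' each sampled in three consecutive years. Base ages are spread evenly over
#' the stated ranges (the true site ages are not published); model
#' parameters come from [succession_presets()].
#'
#' @param catch_mean,overdispersion,seed Passed to every [sim_design()].
#' @return Named list of `sim_design` objects.
#' @examples
#' designs <- design_presets(seed = 7)
#' length(designs$forest_soil_planted$base_ages) # 14 sites
#' @export
design_presets <- function(catch_mean = 200, overdispersion = 0, seed = 1) {
  ranges <- list(
    forest_soil_planted = list(n = 14L, lo = 21, hi = 119),
    post_agri_natural = list(n = 13L, lo = 0, hi = 64),
    post_agri_planted = list(n = 69L, lo = 2, hi = 119),
    ash_heap = list(n = 3L, lo = 8, hi = 14),
    mining_heap = list(n = 4L, lo = 3, hi = 23)
  )
  out <- purrr::imap(ranges, function(r, area) {
    ages <- round(seq(r$lo, r$hi, length.out = r$n))
    sim_design(area, preset_params(area), base_ages = ages,
               catch_mean = catch_mean, overdispersion = overdispersion,
               seed = seed)
  })
  out
}
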