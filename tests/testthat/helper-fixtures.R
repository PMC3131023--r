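# shared fixture builders; everything is generated in code

noiseless_series <- function(params, ages, n_individuals = 100L) {
  new_mib_series(tibble::tibble(
    site_id = "sim",
    stand_age = as.numeric(ages),
    mib_mg = succession_evaluate(params, ages),
    n_individuals = as.integer(n_individuals),
    reliable = n_individuals >= 25
  ))
}

# one random valid parameter set (initial < recovery guaranteed)
random_params <- function() {
  initial <- runif(1, 5, 100)
  succession_params(
    initial = initial,
    delay = runif(1, 0, 20),
    rate = runif(1, 0.01, 1),
    recovery = initial + runif(1, 10, 400)
  )
}

# small catch table for one site over three consecutive years
toy_catches <- function(base_age = 8, site = "s1", area = "ash_heap") {
  tidyr::expand_grid(
    sampling_year = 2004:2006,
    species = c("small_a", "big_b")
  ) |>
    dplyr::mutate(
      site_id = site, area_type = area, stand_age = base_age,
      count = c(20L, 5L, 18L, 7L, 15L, 10L)
    )
}

toy_masses <- tibble::tibble(
  species = c("small_a", "big_b"),
  mass_mg = c(30, 400)
)

# independent exhaustive permutation generator (insertion method), used as
# the brute-force oracle for the exact Spearman p-value
perms_by_insertion <- function(n) {
  out <- matrix(1L, 1L, 1L)
  if (n == 1L) return(out)
  for (k in 2L:n) {
    grown <- vector("list", nrow(out) * k)
    idx <- 1L
    for (i in seq_len(nrow(out))) {
      for (pos in seq_len(k)) {
        grown[[idx]] <- append(out[i, ], k, after = pos - 1L)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, grown)
  }
  out
}

brute_force_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- perms_by_insertion(length(x))
  rho <- apply(perms, 1L, function(i) stats::cor(rx, ry[i]))
  mean(abs(rho) >= abs(obs) - 1e-12)
}
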