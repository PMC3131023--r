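test_that("MIB is the count-weighted mean mass with the 25-individual flag", {
  one <- function(sp, n) data.frame(species = sp, count = n)
  m <- function(sp, mg) data.frame(species = sp, mass_mg = mg)

  res <- compute_mib(one("a", 30), m("a", 100))
  expect_equal(res$mib_mg, 100)
  expect_true(res$reliable)

  res <- compute_mib(one("a", 10), m("a", 50))
  expect_equal(res$mib_mg, 50)
  expect_false(res$reliable)

  # two-species weighted mean: (20*50 + 30*300) / 50 = 200
  res <- compute_mib(
    data.frame(species = c("a", "b"), count = c(20, 30)),
    m(c("a", "b"), c(50, 300))
  )
  expect_equal(res$mib_mg, 200)
  expect_equal(res$n_individuals, 50L)
  expect_true(res$reliable)

  # the threshold itself is configurable
  res <- compute_mib(one("a", 10), m("a", 50), reliability_threshold = 10)
  expect_true(res$reliable)
})

test_that("empty samples yield missing MIB, not zero", {
  res <- compute_mib(data.frame(species = "a", count = 0),
                     data.frame(species = "a", mass_mg = 50))
  expect_true(is.na(res$mib_mg))
  expect_equal(res$n_individuals, 0L)
  expect_false(res$reliable)
})

test_that("catch validation names offending species and rejects bad counts", {
  masses <- data.frame(species = "a", mass_mg = 50)
  expect_error(
    compute_mib(data.frame(species = c("a", "ghost"), count = c(1, 2)), masses),
    "ghost"
  )
  expect_error(
    compute_mib(data.frame(species = "a", count = -1), masses),
    "negative"
  )
  expect_error(
    compute_mib(data.frame(species = "a", count = 1),
                data.frame(species = "a", mass_mg = 0)),
    "positive"
  )
})

test_that("MIB is invariant to splitting records and bounded by species masses", {
  set.seed(101)
  masses <- data.frame(species = letters[1:6],
                       mass_mg = runif(6, 10, 500))
  for (rep in 1:20) {
    catches <- data.frame(
      species = sample(letters[1:6], 4),
      count = sample(1:50, 4)
    )
    base <- compute_mib(catches, masses)

    # split the first record into two rows whose counts sum to the original
    k <- sample(0:catches$count[1], 1)
    split <- rbind(
      transform(catches[1, ], count = k),
      transform(catches[1, ], count = catches$count[1] - k),
      catches[-1, ]
    )
    expect_identical(compute_mib(split, masses)$mib_mg, base$mib_mg)

    present <- masses$mass_mg[masses$species %in% catches$species[catches$count > 0]]
    expect_gte(base$mib_mg, min(present))
    expect_lte(base$mib_mg, max(present))
  }
})

test_that("series points sit at consecutive ages from the site's base age", {
  s <- build_mib_series(toy_catches(base_age = 8), toy_masses)
  expect_s3_class(s, "mib_series")
  expect_equal(s$stand_age, c(8, 9, 10))
  expect_equal(attr(s, "area_type"), "ash_heap")
  # MIB per year: (20*30+5*400)/25, (18*30+7*400)/25, (15*30+10*400)/25
  expect_equal(s$mib_mg, c(2600, 3340, 4450) / 25)
  expect_true(all(s$reliable))
})

test_that("series handles one-point, multi-site and degenerate inputs", {
  one_year <- toy_catches()[toy_catches()$sampling_year == 2004, ]
  expect_equal(nrow(build_mib_series(one_year, toy_masses)), 1L)

  two_sites <- rbind(toy_catches(base_age = 8, site = "s1"),
                     toy_catches(base_age = 30, site = "s2"))
  s <- build_mib_series(two_sites, toy_masses)
  expect_equal(nrow(s), 6L)
  expect_equal(s$stand_age, c(8, 9, 10, 30, 31, 32))
  expect_true(!is.unsorted(s$stand_age))

  expect_error(build_mib_series(toy_catches()[0, ], toy_masses), "empty")
  mixed <- rbind(toy_catches(area = "ash_heap"),
                 toy_catches(site = "s9", area = "mining_heap"))
  expect_error(build_mib_series(mixed, toy_masses), "area types")
})

test_that("Spearman statistic matches perfect monotone cases and errors", {
  mk <- function(age, mib) new_mib_series(tibble::tibble(
    site_id = "x", stand_age = age, mib_mg = mib,
    n_individuals = 30L, reliable = TRUE))

  expect_equal(spearman_mib_age(mk(1:4, c(10, 20, 30, 40)))$rho, 1)
  expect_equal(spearman_mib_age(mk(1:4, c(40, 30, 20, 10)))$rho, -1)

  expect_error(spearman_mib_age(mk(1:2, c(1, 2))), "at least 3")
  expect_error(spearman_mib_age(mk(c(1, 1, 1), c(1, 2, 3))), "variance")
  expect_error(spearman_mib_age(mk(1:3, c(5, 5, 5))), "variance")
})

test_that("unreliable points can be excluded from the correlation", {
  s <- new_mib_series(tibble::tibble(
    site_id = "x", stand_age = 1:6,
    mib_mg = c(10, 20, 30, 40, 50, 5),
    n_individuals = c(rep(30L, 5), 3L),
    reliable = c(rep(TRUE, 5), FALSE)
  ))
  keep <- spearman_mib_age(s, include_unreliable = TRUE)
  drop <- spearman_mib_age(s, include_unreliable = FALSE)
  expect_equal(keep$n, 6L)
  expect_equal(drop$n, 5L)
  expect_equal(drop$rho, 1)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(202)
  for (rep in 1:10) {
    age <- sample(1:50, 8)
    mib <- runif(8, 20, 400)
    s <- function(a, m) new_mib_series(tibble::tibble(
      site_id = "x", stand_age = a, mib_mg = m,
      n_individuals = 30L, reliable = TRUE))
    base <- spearman_mib_age(s(age, mib))
    warped <- spearman_mib_age(s(age^2, exp(mib / 100)))
    expect_equal(warped$rho, base$rho)
    expect_equal(warped$p_value, base$p_value)
  }
})

test_that("exact permutation p-value agrees with brute force for n <= 7", {
  set.seed(303)
  for (n in 3:7) {
    for (rep in 1:5) {
      age <- sample(1:100, n)
      mib <- c(runif(n - 1, 10, 500),
               if (rep %% 2 == 0) NA else runif(1, 10, 500))
      mib[is.na(mib)] <- mib[1] # every other rep contains a tie
      s <- new_mib_series(tibble::tibble(
        site_id = "x", stand_age = age, mib_mg = mib,
        n_individuals = 30L, reliable = TRUE))
      res <- spearman_mib_age(s)
      expect_equal(res$method, "exact permutation")
      expect_equal(res$p_value, brute_force_spearman_p(age, mib))
    }
  }
})

test_that("exact p-value matches the reference implementation on untied data", {
  set.seed(404)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    age <- sample(1:1000, n)
    mib <- runif(n, 10, 500)
    s <- new_mib_series(tibble::tibble(
      site_id = "x", stand_age = age, mib_mg = mib,
      n_individuals = 30L, reliable = TRUE))
    ours <- spearman_mib_age(s)
    ref <- stats::cor.test(age, mib, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})
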