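test_that("species medians aggregate per species and ignore row order", {
  d <- tibble::tibble(
    species = c("Alpha one", "Beta two", "Beta two", "Beta two"),
    basic_density = c(0.3, 0.4, 0.6, 0.8))
  s <- species_medians(d)
  expect_equal(s$median_density, c(0.3, 0.6))
  expect_equal(s$n_samples, c(1L, 3L))
  perm <- d[c(3, 1, 4, 2), ]
  expect_equal(species_medians(perm), s)
  # median stays within each species' sample range
  g <- generate_core_dataset(synthetic_config(n_species = 50, seed = 8))
  ss <- species_medians(g$records)
  rng <- dplyr::summarise(dplyr::group_by(g$records, species),
                          lo = min(basic_density), hi = max(basic_density))
  j <- dplyr::inner_join(ss, rng, by = "species")
  expect_true(all(j$median_density >= j$lo & j$median_density <= j$hi))
})

test_that("density classification uses half-open thresholds at 0.4 and 0.75", {
  expect_equal(as.character(classify_density(0.197)), "low")
  expect_equal(as.character(classify_density(0.530)), "medium")
  expect_equal(as.character(classify_density(0.866)), "high")
  expect_equal(as.character(classify_density(c(0.40, 0.75))),
               c("medium", "high"))
  expect_error(classify_density(0), "positive")
  # total on (0, Inf): every positive value gets exactly one class
  withr::with_seed(1, x <- runif(500, 1e-6, 2))
  expect_false(anyNA(classify_density(x)))
})

test_that("class counts conserve the number of species", {
  s <- tibble::tibble(median_density = c(0.2, 0.5, 0.8))
  expect_equal(class_counts(s),
               c(n_low = 1L, n_medium = 1L, n_high = 1L))
  expect_equal(class_counts(s[0, ]), c(n_low = 0L, n_medium = 0L, n_high = 0L))
  for (seed in 1:3) {
    r <- random_summaries(200, seed)
    expect_equal(sum(class_counts(r)), 200L)
  }
})

test_that("extreme-species ranking agrees with a full-sort oracle", {
  for (seed in 1:5) {
    s <- random_summaries(30, seed)
    got <- extreme_species(s, min_n = 3, k = 4, direction = "lightest")
    pool <- s[s$n_samples >= 3, ]
    oracle <- pool[order(pool$median_density, pool$species), ]
    expect_equal(got$species, utils::head(oracle$species, 4))
    got_h <- extreme_species(s, min_n = 3, k = 4, direction = "heaviest")
    oracle_h <- pool[order(-pool$median_density, pool$species), ]
    expect_equal(got_h$species, utils::head(oracle_h$species, 4))
  }
  s <- random_summaries(10, 99)
  expect_equal(nrow(extreme_species(s, min_n = 99)), 0)
})

test_that("histogram bins are half-open, conserve species and match class totals", {
  s <- tibble::tibble(median_density = c(0.05, 0.06))
  h <- density_histogram(s, 0.05)
  expect_equal(h$count[h$bin_start == 0.05], 2L)
  for (seed in 1:3) {
    r <- random_summaries(150, seed)
    h <- density_histogram(r, 0.05)
    expect_equal(sum(h$count), 150L)
    by_class <- tapply(h$count, h$class, sum, default = 0L)
    cc <- class_counts(r)
    expect_equal(as.integer(by_class[c("low", "medium", "high")]),
                 as.integer(cc))
  }
})

test_that("variance partition handles degenerate and invalid designs", {
  d <- tibble::tibble(species = rep(c("a", "b"), each = 2),
                      basic_density = c(0.4, 0.4, 0.8, 0.8))
  vp <- variance_partition(d)
  expect_equal(vp$pct_among_species, 100)
  expect_equal(vp$pct_within_species, 0)
  expect_equal(vp$pct_among_species + vp$pct_within_species, 100)
  expect_error(variance_partition(d[1:2, ]), "at least 2 species")
  # singletons are excluded before estimation
  d2 <- dplyr::bind_rows(d, tibble::tibble(species = "c", basic_density = 5))
  expect_equal(variance_partition(d2)$n_species_used, 2)
})

test_that("variance-partition mean squares agree with an independent ANOVA fit", {
  withr::with_seed(31, {
    k <- 25
    ni <- sample(2:9, k, replace = TRUE)
    sp <- rep(sprintf("sp%02d", seq_len(k)), ni)
    x <- rep(rnorm(k, 0.5, 0.12), ni) + rnorm(sum(ni), 0, 0.07)
  })
  d <- tibble::tibble(species = sp, basic_density = x)
  vp <- variance_partition(d)
  fit <- stats::aov(basic_density ~ species, data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  N <- sum(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  va <- max(0, (ms[1] - ms[2]) / n0)
  expect_equal(vp$var_within, ms[2], tolerance = 1e-12)
  expect_equal(vp$var_among, va, tolerance = 1e-12)
  # and with a REML fit as a second, independent route
  if (requireNamespace("lme4", quietly = TRUE)) {
    fit2 <- lme4::lmer(basic_density ~ 1 | species, data = d)
    vc <- as.data.frame(lme4::VarCorr(fit2))
    pct_reml <- 100 * vc$vcov[1] / sum(vc$vcov)
    expect_equal(vp$pct_among_species, pct_reml, tolerance = 0.08)
  }
})

test_that("variance-partition estimator is close to unbiased in simulation", {
  truth <- 69
  tot <- 0.02
  ests <- vapply(1:100, function(r) {
    withr::with_seed(1000 + r, {
      k <- 100
      n <- 5
      mu <- rnorm(k, 0.53, sqrt(tot * truth / 100))
      x <- rep(mu, each = n) + rnorm(k * n, 0, sqrt(tot * (1 - truth / 100)))
    })
    d <- tibble::tibble(species = rep(sprintf("s%03d", 1:k), each = n),
                        basic_density = x)
    variance_partition(d)$pct_among_species
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 1)
})
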