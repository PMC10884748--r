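# Seeded forward-model generator of synthetic core-sample and site
# datasets with the statistical structure of the national inventory
# tables. The forward model inverts the shrinkage theory exactly, so a
# zero-noise generate -> process round trip recovers the generating basic
# density to machine precision; instrument noise (balance 0.001 g,
# caliper 0.01 mm) can be switched on to emulate measurement error.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the marginal structure of the national wood-density
#' and site tables: species basic specific gravities from a truncated
#' normal (mean 0.53, sd 0.14) on (0.05, 0.95); samples per species from
#' a zipf-like discrete law (exponent 1.7, capped at 177; median 2, mean
#' about 6.7); eliminated moisture from a gamma (shape 4, scale 2.44,
#' capped at 95%; median about 9%); core lengths log-normal around a
#' 6.11 cm median within 0.56--26.99 cm; a 0.508 cm borer; trees per site
#' from a zipf-like law (exponent 1.6, capped at 33; median 2); and
#' joint height/diameter missingness of 7.4%. The within-species
#' coefficient of variation (0.17) is calibrated so that roughly 69% of
#' total density variance lies among species.
#'
#' @param n_species Number of species in the pool.
#' @param seed Integer seed; every generator call is reproducible under
#'   it.
#' @param gravity_mean,gravity_sd,gravity_support Truncated-normal law of
#'   species basic specific gravity.
#' @param within_species_cv Within-species coefficient of variation of
#'   gravity.
#' @param samples_per_species_exponent,samples_per_species_max Zipf-like
#'   law of core samples per species.
#' @param moisture_shape,moisture_scale,moisture_max_pct Gamma law of
#'   eliminated moisture (%), truncated at `moisture_max_pct`.
#' @param length_meanlog,length_sdlog,length_support_cm Log-normal law of
#'   core length (cm), truncated to the support.
#' @param borer_diameter_cm Nominal borer bore; default 0.508 cm.
#' @param diameter_jitter_mm Scale (sd) of the volume-preserving elliptic
#'   deformation of the dried core's cross-section.
#' @param balance_sd_g,caliper_sd_mm Instrument noise scales (additive,
#'   applied only when `noise = TRUE`).
#' @param noise Apply instrument noise? Default `FALSE`.
#' @param n_sites Number of sites for [generate_site_dataset()].
#' @param lat_range,lon_range Bounding box of site coordinates (decimal
#'   degrees WGS84).
#' @param trees_per_site_exponent,trees_per_site_max Zipf-like law of
#'   trees per site.
#' @param missing_frac Joint missingness fraction of height and dbh.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species = 200,
                             seed = 1L,
                             gravity_mean = 0.53,
                             gravity_sd = 0.14,
                             gravity_support = c(0.05, 0.95),
                             within_species_cv = 0.17,
                             samples_per_species_exponent = 1.7,
                             samples_per_species_max = 177L,
                             moisture_shape = 4,
                             moisture_scale = 2.44,
                             moisture_max_pct = 95,
                             length_meanlog = log(6.11),
                             length_sdlog = 0.33,
                             length_support_cm = c(0.56, 26.99),
                             borer_diameter_cm = 0.508,
                             diameter_jitter_mm = 0.05,
                             balance_sd_g = 0.001,
                             caliper_sd_mm = 0.01,
                             noise = FALSE,
                             n_sites = 400,
                             lat_range = c(14.5, 32.5),
                             lon_range = c(-116.6, -86.8),
                             trees_per_site_exponent = 1.6,
                             trees_per_site_max = 33L,
                             missing_frac = 0.074) {
  cfg <- as.list(environment())
  if (cfg$n_species < 1) stop("`n_species` must be >= 1", call. = FALSE)
  scales <- c(cfg$within_species_cv, cfg$diameter_jitter_mm,
              cfg$balance_sd_g, cfg$caliper_sd_mm, cfg$missing_frac)
  if (any(scales < 0)) stop("noise/scale parameters must be >= 0",
                            call. = FALSE)
  if (cfg$gravity_support[1] <= 0 ||
      cfg$gravity_support[1] >= cfg$gravity_support[2]) {
    stop("`gravity_support` must be an increasing positive interval",
         call. = FALSE)
  }
  if (cfg$borer_diameter_cm <= 0) {
    stop("`borer_diameter_cm` must be positive", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "synthetic_config")
}

# rejection sampling into [lo, hi]; rfun(k) must draw k iid values
.rtrunc <- function(n, rfun, lo, hi) {
  x <- rfun(n)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0) {
    x[bad] <- rfun(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1L
    if (tries > 10000L) stop("truncation rejection did not converge",
                             call. = FALSE)
  }
  x
}

# per-element truncated normal with vector means/sds (keeps alignment
# between redraws and their target element)
.rtruncnorm_vec <- function(means, sds, lo, hi) {
  n <- length(means)
  x <- stats::rnorm(n, means, sds)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), means[bad], sds[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1L
    if (tries > 10000L) stop("truncation rejection did not converge",
                             call. = FALSE)
  }
  x
}

.rzipf <- function(n, exponent, max) {
  sample.int(max, n, replace = TRUE, prob = seq_len(max)^(-exponent))
}

# unseeded internals -----------------------------------------------------

.species_pool <- function(config) {
  n <- config$n_species
  genus <- sprintf("Genus%03d", (seq_len(n) - 1L) %/% 3L + 1L)
  species <- paste(genus, sprintf("syntheticum%04d", seq_len(n)))
  family <- sprintf("Family%02d", ((seq_len(n) - 1L) %/% 9L) %% 40L + 1L)
  gravity <- .rtrunc(n,
                     function(k) stats::rnorm(k, config$gravity_mean,
                                              config$gravity_sd),
                     config$gravity_support[1], config$gravity_support[2])
  tibble::tibble(species_id = seq_len(n), species = species, genus = genus,
                 family = family, true_gravity = gravity)
}

.site_grid <- function(config, n_sites) {
  veg <- setdiff(major_forest_types, "Mangrove and wetland forest")
  tibble::tibble(
    upmid = sort(sample.int(311922L, n_sites)),
    latitude = round(stats::runif(n_sites, config$lat_range[1],
                                  config$lat_range[2]), 4),
    longitude = round(stats::runif(n_sites, config$lon_range[1],
                                   config$lon_range[2]), 4),
    elevation_m = round(stats::runif(n_sites, -13, 3944)),
    state = sprintf("State%02d", sample.int(32L, n_sites, replace = TRUE)),
    municipality = sprintf("Municipality%03d",
                           sample.int(300L, n_sites, replace = TRUE)),
    major_forest_vegetation_type = sample(veg, n_sites, replace = TRUE,
                                          prob = c(31, 22, 19, 11, 3, 9, 5)),
    floristic_province = sample(floristic_provinces, n_sites, replace = TRUE)
  )
}

.rdates <- function(n, from = as.Date("2013-04-01"),
                    to = as.Date("2015-10-31")) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate a reproducible species pool with true basic gravities
#'
#' @param config A [synthetic_config()].
#' @return A tibble `(species_id, species, genus, family, true_gravity)`
#'   with `n_species` rows; gravities lie inside `gravity_support`.
#'   Identical for identical seeds.
#' @export
generate_species_pool <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .species_pool(config))
}

#' Forward-simulate core-sample measurements from known truth
#'
#' Inverts the laboratory chain as a generative model: the green volume
#' follows from the borer bore and length; the oven-dry mass is
#' `Gb * V_green` (the shrinkage model maps specific gravity to ambient
#' density on a numerically density-like scale, so its exact forward
#' image uses `Gb`, not `Gb * water_density`); the ambient mass adds the
#' water fraction `w`; and the measured (dried) volume is the green
#' volume scaled by `1 - slope * Gb * max(0, fsp - w)/fsp`. Diameters are
#' back-computed from the measured volume, optionally deformed into a
#' volume-preserving ellipse (`diameter_jitter_mm`) and perturbed by
#' instrument noise. With zero noise, [process_core_samples()] in
#' derivation-consistent piecewise mode recovers the true basic density
#' `Gb * water_density` exactly.
#'
#' Jitter and noise draw from the session RNG; seed the caller (see
#' [generate_core_dataset()]) for reproducibility.
#'
#' @param true_gravity Basic specific gravity per sample. Vectorised.
#' @param moisture_pct Water content per sample, % in \[0, 200\].
#' @param length_cm Core length per sample, cm.
#' @param params A [conversion_params()]; supplies the shrinkage slope,
#'   water density and fiber-saturation point of the generative model.
#' @param borer_diameter_cm Nominal bore; default 0.508 cm.
#' @param diameter_jitter_mm Sd of the elliptic deformation; default 0.
#' @param balance_sd_g,caliper_sd_mm Additive instrument noise; default 0.
#' @param sample_id Optional ids; defaults to `S000001`, ...
#' @return A tibble of measurements (`sample_id`, `length_cm`,
#'   `d_min_mm`, `d_max_mm`, `mass_ambient_g`, `mass_ovendry_g`) plus the
#'   true `green_volume_cm3`.
#' @export
forward_measurement <- function(true_gravity, moisture_pct, length_cm,
                                params = conversion_params(
                                  numerator_mode = "derivation_consistent",
                                  moisture_model = "piecewise_fiber_saturation"),
                                borer_diameter_cm = 0.508,
                                diameter_jitter_mm = 0,
                                balance_sd_g = 0,
                                caliper_sd_mm = 0,
                                sample_id = NULL) {
  stopifnot(inherits(params, "conversion_params"))
  n <- max(length(true_gravity), length(moisture_pct), length(length_cm))
  gb <- rep_len(true_gravity, n)
  w <- rep_len(moisture_pct, n)
  l <- rep_len(length_cm, n)
  if (any(!is.finite(gb)) || any(gb <= 0)) {
    stop("`true_gravity` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0) || any(w > 200)) {
    stop("`moisture_pct` must lie in [0, 200]", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sprintf("S%06d", seq_len(n))

  s <- params$shrinkage_slope
  fsp <- params$fiber_saturation_pct
  shrink <- 1 - s * gb * pmax(0, fsp - w) / fsp
  if (any(shrink <= 0)) {
    stop("shrinkage factor <= 0 in forward model", call. = FALSE)
  }

  v_green <- pi * (borer_diameter_cm / 2)^2 * l
  m2 <- gb * v_green
  m1 <- m2 * (1 + w / 100)
  v_meas <- v_green * shrink

  d_mm <- sqrt(400 * v_meas / (pi * l))
  if (diameter_jitter_mm > 0) {
    j <- pmin(abs(stats::rnorm(n, 0, diameter_jitter_mm)), 0.5 * d_mm)
    d_min <- d_mm - j
    d_max <- d_mm^2 / d_min  # preserves d_min * d_max = d^2, hence volume
  } else {
    d_min <- d_max <- d_mm
  }
  if (caliper_sd_mm > 0) {
    d_min <- d_min + stats::rnorm(n, 0, caliper_sd_mm)
    d_max <- pmax(d_max + stats::rnorm(n, 0, caliper_sd_mm), d_min)
    l <- pmax(l + stats::rnorm(n, 0, caliper_sd_mm / 10), 0.01)
  }
  if (balance_sd_g > 0) {
    m2 <- pmax(m2 + stats::rnorm(n, 0, balance_sd_g), 1e-4)
    m1 <- pmax(m1 + stats::rnorm(n, 0, balance_sd_g), m2)
  }

  tibble::tibble(sample_id = sample_id, length_cm = l, d_min_mm = d_min,
                 d_max_mm = d_max, mass_ambient_g = m1,
                 mass_ovendry_g = m2, green_volume_cm3 = v_green)
}

#' Generate a synthetic wood-density dataset with retained truth
#'
#' Draws a species pool, per-species sample counts, per-sample gravities
#' (within-species variation), moisture and lengths; forward-simulates
#' the measurements; processes them with [process_core_samples()] under
#' `params`; and assembles records in the wood-density table layout with
#' synthetic locality fields. The generating truth is returned alongside,
#' so parameter recovery can be checked end to end.
#'
#' @param config A [synthetic_config()].
#' @param params Conversion parameters used to derive the recorded basic
#'   densities; default [conversion_params()] (the published uniform
#'   closed form, emulating how the deposited values were computed). Pass
#'   derivation-consistent piecewise parameters for exact zero-noise
#'   recovery.
#' @return A list: `records` (tibble in the `"densities"` schema),
#'   `truth` (tibble with `sample_id`, `species`, per-sample
#'   `true_gravity`, `true_basic_density = true_gravity * water_density`,
#'   `green_volume_cm3`, `true_moisture_pct`), and `measurements` (the
#'   raw simulated readings).
#' @export
generate_core_dataset <- function(config = synthetic_config(),
                                  params = conversion_params()) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "conversion_params"))
  withr::with_seed(config$seed, {
    pool <- .species_pool(config)
    n_i <- .rzipf(config$n_species, config$samples_per_species_exponent,
                  config$samples_per_species_max)
    idx <- rep(pool$species_id, n_i)
    n <- length(idx)

    gb <- .rtruncnorm_vec(pool$true_gravity[idx],
                          config$within_species_cv * pool$true_gravity[idx],
                          config$gravity_support[1],
                          config$gravity_support[2])
    w <- .rtrunc(n, function(k) stats::rgamma(k, shape = config$moisture_shape,
                                              scale = config$moisture_scale),
                 0, config$moisture_max_pct)
    l <- .rtrunc(n, function(k) stats::rlnorm(k, config$length_meanlog,
                                              config$length_sdlog),
                 config$length_support_cm[1], config$length_support_cm[2])

    meas <- forward_measurement(
      gb, w, l, params = params,
      borer_diameter_cm = config$borer_diameter_cm,
      diameter_jitter_mm = config$diameter_jitter_mm,
      balance_sd_g = if (config$noise) config$balance_sd_g else 0,
      caliper_sd_mm = if (config$noise) config$caliper_sd_mm else 0)

    proc <- process_core_samples(meas[, 1:6], params)

    n_sites <- max(1L, round(n / 2.7))
    sites <- .site_grid(config, n_sites)
    site_of <- sample.int(n_sites, n, replace = TRUE)

    miss <- stats::runif(n) < config$missing_frac
    height <- .rtrunc(n, function(k) stats::rlnorm(k, log(8.0), 0.51), 1.3, 37)
    dbh <- .rtrunc(n, function(k) stats::rlnorm(k, log(17.1), 0.55), 3.9, 237)
    height[miss] <- NA_real_
    dbh[miss] <- NA_real_

    records <- tibble::tibble(
      collection_code = sprintf("SYN-%05d", seq_len(n)),
      species = pool$species[idx],
      author = "Synth.",
      genus = pool$genus[idx],
      family = pool$family[idx],
      basic_density = proc$basic_density,
      length_cm = proc$length_cm,
      volume_cm3 = proc$volume_cm3,
      density_ambient = proc$density_ambient,
      moisture_pct = proc$moisture_pct,
      upmid = sites$upmid[site_of],
      latitude = sites$latitude[site_of],
      longitude = sites$longitude[site_of],
      elevation_m = sites$elevation_m[site_of],
      state = sites$state[site_of],
      municipality = sites$municipality[site_of],
      major_forest_vegetation_type =
        sites$major_forest_vegetation_type[site_of],
      floristic_province = sites$floristic_province[site_of],
      collection_date = .rdates(n),
      taxonomist = sprintf("Taxonomist%02d",
                           sample.int(5L, n, replace = TRUE)),
      height_m = round(height, 1),
      dbh_cm = round(dbh, 1)
    )
    truth <- tibble::tibble(
      sample_id = meas$sample_id,
      species = pool$species[idx],
      true_gravity = gb,
      true_basic_density = gb * params$water_density,
      green_volume_cm3 = meas$green_volume_cm3,
      true_moisture_pct = w
    )
    list(records = records, truth = truth, measurements = meas[, 1:6])
  })
}

#' Generate a synthetic tree site-location dataset
#'
#' Sites fall uniformly in the configured bounding box (defaults: lat
#' 14.5--32.5, lon -116.6 to -86.8); per-site tree counts follow the
#' heavy-tailed trees-per-site law; heights and diameters follow
#' truncated log-normal laws within the observed 1--42 m and 3--421 cm
#' ranges, jointly missing with probability `missing_frac`.
#'
#' @param config A [synthetic_config()].
#' @return A tibble in the `"sites"` schema, one row per tree.
#' @export
generate_site_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    pool <- .species_pool(config)
    sites <- .site_grid(config, config$n_sites)
    trees_per_site <- .rzipf(config$n_sites, config$trees_per_site_exponent,
                             config$trees_per_site_max)
    site_of <- rep(seq_len(config$n_sites), trees_per_site)
    n <- length(site_of)
    sp <- .rzipf(n, 1.2, config$n_species)  # common species dominate

    miss <- stats::runif(n) < config$missing_frac
    height <- .rtrunc(n, function(k) stats::rlnorm(k, log(7.1), 0.514), 1, 42)
    dbh <- .rtrunc(n, function(k) stats::rlnorm(k, log(14.9), 0.712), 3, 421)
    height[miss] <- NA_real_
    dbh[miss] <- NA_real_

    tibble::tibble(
      collection_code = sprintf("SYN-%05d", seq_len(n)),
      species = pool$species[sp],
      author = "Synth.",
      genus = pool$genus[sp],
      family = pool$family[sp],
      upmid = sites$upmid[site_of],
      latitude = sites$latitude[site_of],
      longitude = sites$longitude[site_of],
      elevation_m = sites$elevation_m[site_of],
      state = sites$state[site_of],
      municipality = sites$municipality[site_of],
      major_forest_vegetation_type =
        sites$major_forest_vegetation_type[site_of],
      floristic_province = sites$floristic_province[site_of],
      collection_date = .rdates(n, as.Date("2009-03-01"),
                                as.Date("2017-10-31")),
      taxonomist = sprintf("Taxonomist%02d",
                           sample.int(5L, n, replace = TRUE)),
      height_m = round(height, 1),
      dbh_cm = round(dbh, 1)
    )
  })
}
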