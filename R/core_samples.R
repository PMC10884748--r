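# Core-sample processing: from caliper and balance readings on an
# increment-borer core (nominal bore 0.508 cm) to basic wood-density.
# The measurement chain is: elliptic-cylinder volume -> ambient density ->
# eliminated moisture -> basic density via the closed-form conversion.

# Plausibility windows: observed dataset ranges widened by 10%. These
# describe one national inventory, not physical limits, so violations
# reject the row with a reason rather than raising an error.
.core_plausibility <- list(
  d_mm      = c(2.5, 8.0),                       # around the 5.08 mm bore
  length_cm = c(0.56 * 0.9, 26.99 * 1.1)
)

#' Elliptic-cylinder volume of a core sample
#'
#' Increment-borer cores are nominally circular (bore 0.508 cm) but may
#' deform slightly on drying, so two perpendicular diameters are measured
#' and the cross-section treated as an ellipse:
#' `volume = d_min * d_max * pi * l / 400` with diameters in mm and length
#' in cm, giving cm3. The formula depends on the diameters only through
#' their product, so it is symmetric in (`d_min`, `d_max`).
#'
#' @param length_cm Core length in cm (> 0). Vectorised.
#' @param d_min_mm,d_max_mm Minimum and maximum transversal diameters, mm
#'   (> 0).
#' @return Volume in cm3.
#' @examples
#' elliptic_volume(1, 5.08, 5.08)  # 0.2027 cm3, the nominal bore
#' @export
elliptic_volume <- function(length_cm, d_min_mm, d_max_mm) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("`length_cm` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(d_min_mm)) || any(d_min_mm <= 0) ||
      any(!is.finite(d_max_mm)) || any(d_max_mm <= 0)) {
    stop("diameters must be finite and positive", call. = FALSE)
  }
  d_min_mm * d_max_mm * pi * length_cm / 400
}

#' Eliminated moisture of a core sample
#'
#' Water content as a percentage of oven-dry mass:
#' `w = 100 * (m1 - m2) / m2`, where `m1` is the ambient mass and `m2` the
#' mass after oven-drying (105 degrees C, 48 h).
#'
#' @param mass_ambient_g Mass at ambient humidity, g. Vectorised.
#' @param mass_ovendry_g Oven-dry mass, g (> 0, and not exceeding
#'   `mass_ambient_g`: a sample cannot gain mass in the oven).
#' @return Water content in %.
#' @export
moisture_percent <- function(mass_ambient_g, mass_ovendry_g) {
  if (any(!is.finite(mass_ovendry_g)) || any(mass_ovendry_g <= 0)) {
    stop("`mass_ovendry_g` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(mass_ambient_g)) ||
      any(mass_ambient_g < mass_ovendry_g)) {
    stop("`mass_ambient_g` must be finite and >= `mass_ovendry_g` ",
         "(mass cannot be gained in the oven)", call. = FALSE)
  }
  100 * (mass_ambient_g - mass_ovendry_g) / mass_ovendry_g
}

#' Ambient-state density of a core sample
#'
#' Mass at ambient humidity divided by the measured (ambient) volume.
#'
#' @param mass_ambient_g Mass at ambient humidity, g. Vectorised.
#' @param volume_cm3 Measured volume, cm3 (> 0).
#' @return Density in g/cm3.
#' @export
ambient_density <- function(mass_ambient_g, volume_cm3) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0)) {
    stop("`volume_cm3` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(mass_ambient_g)) || any(mass_ambient_g <= 0)) {
    stop("`mass_ambient_g` must be finite and positive", call. = FALSE)
  }
  mass_ambient_g / volume_cm3
}

#' Process a table of core-sample measurements
#'
#' Runs the full laboratory chain on a table of raw readings: volume from
#' length and two diameters, ambient density, eliminated moisture, and
#' basic wood-density via [basic_from_ambient()]. Each row is screened
#' first: mathematically invalid rows (non-positive dimensions or masses,
#' `d_min > d_max`, ambient mass below oven-dry mass) and rows outside the
#' plausibility windows (diameters in (2.5, 8.0) mm around the 5.08 mm
#' bore; lengths within the observed 0.56--26.99 cm range widened by 10%)
#' are rejected with a recorded reason; derived columns are `NA` for
#' rejected rows. Duplicate `sample_id`s are an error, since the protocol
#' takes one sample per tree.
#'
#' @param measurements A data frame with columns `sample_id`, `length_cm`,
#'   `d_min_mm`, `d_max_mm`, `mass_ambient_g`, `mass_ovendry_g`.
#' @param params A [conversion_params()] object for the basic-density
#'   conversion.
#' @param plausibility Apply the plausibility windows? Default `TRUE`.
#' @return A tibble: the input columns plus `volume_cm3`,
#'   `density_ambient`, `moisture_pct`, `basic_density`, `accepted`
#'   (logical) and `violations` (semicolon-separated reasons, `""` if
#'   none). By construction `density_ambient * volume_cm3` equals
#'   `mass_ambient_g` for accepted rows.
#' @examples
#' m <- tibble::tibble(sample_id = "a", length_cm = 1, d_min_mm = 5.08,
#'                     d_max_mm = 5.08, mass_ambient_g = 0.10907,
#'                     mass_ovendry_g = 0.10007)
#' process_core_samples(m)
#' @export
process_core_samples <- function(measurements,
                                 params = conversion_params(),
                                 plausibility = TRUE) {
  stopifnot(inherits(params, "conversion_params"))
  req <- c("sample_id", "length_cm", "d_min_mm", "d_max_mm",
           "mass_ambient_g", "mass_ovendry_g")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols) > 0) {
    stop("`measurements` lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- tibble::as_tibble(measurements)
  if (anyDuplicated(m$sample_id)) {
    dup <- unique(m$sample_id[duplicated(m$sample_id)])
    stop("duplicate sample_id (one sample per tree expected): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  n <- nrow(m)
  reasons <- vector("list", n)
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  bad <- function(x) !is.finite(x)
  add(bad(m$length_cm) | m$length_cm <= 0, "non-positive or missing length")
  add(bad(m$d_min_mm) | m$d_min_mm <= 0 |
        bad(m$d_max_mm) | m$d_max_mm <= 0,
      "non-positive or missing diameter")
  add(!bad(m$d_min_mm) & !bad(m$d_max_mm) & m$d_min_mm > m$d_max_mm,
      "d_min exceeds d_max")
  add(bad(m$mass_ovendry_g) | m$mass_ovendry_g <= 0,
      "non-positive or missing oven-dry mass")
  add(!bad(m$mass_ambient_g) & !bad(m$mass_ovendry_g) &
        m$mass_ambient_g < m$mass_ovendry_g,
      "mass gained in oven (m1 < m2)")
  add(bad(m$mass_ambient_g), "missing ambient mass")

  if (isTRUE(plausibility)) {
    dwin <- .core_plausibility$d_mm
    lwin <- .core_plausibility$length_cm
    add(!bad(m$d_min_mm) & !bad(m$d_max_mm) &
          (m$d_min_mm <= dwin[1] | m$d_max_mm >= dwin[2]),
        sprintf("diameter outside plausibility window (%.1f, %.1f) mm",
                dwin[1], dwin[2]))
    add(!bad(m$length_cm) & m$length_cm > 0 &
          (m$length_cm < lwin[1] | m$length_cm > lwin[2]),
        sprintf("length outside plausibility window [%.3f, %.3f] cm",
                lwin[1], lwin[2]))
  }

  accepted <- vapply(reasons, function(r) is.null(r), logical(1))
  violations <- vapply(reasons, function(r) {
    if (is.null(r)) "" else paste(r, collapse = "; ")
  }, character(1))

  volume_cm3 <- density_ambient <- moisture_pct <- basic_density <-
    rep(NA_real_, n)
  if (any(accepted)) {
    a <- accepted
    volume_cm3[a] <- elliptic_volume(m$length_cm[a], m$d_min_mm[a],
                                     m$d_max_mm[a])
    density_ambient[a] <- ambient_density(m$mass_ambient_g[a], volume_cm3[a])
    moisture_pct[a] <- moisture_percent(m$mass_ambient_g[a],
                                        m$mass_ovendry_g[a])
    w_capped <- pmin(moisture_pct[a], 200)
    basic_density[a] <- basic_from_ambient(density_ambient[a], w_capped,
                                           params)
  }

  dplyr::mutate(m,
                volume_cm3 = volume_cm3,
                density_ambient = density_ambient,
                moisture_pct = moisture_pct,
                basic_density = basic_density,
                accepted = accepted,
                violations = violations)
}

# observed dataset ranges for derived quantities (densities table)
.derived_ranges <- list(
  volume_cm3      = c(0.097, 5.470),
  basic_density   = c(0.047, 0.925),
  moisture_pct    = c(0,     92.5),
  density_ambient = c(0.059, 1.243)
)

#' Screen derived core-sample quantities against observed ranges
#'
#' Compares derived quantities against the observed ranges of the national
#' wood-density dataset (volume 0.097--5.470 cm3, basic density
#' 0.047--0.925 g/cm3, moisture 0--92.5%, ambient density 0.059--1.243
#' g/cm3), widened by a relative `tolerance` on each side. Moisture keeps a
#' hard lower bound of zero: negative moisture is physically impossible.
#'
#' @param derived A data frame with any of the columns `volume_cm3`,
#'   `basic_density`, `moisture_pct`, `density_ambient` (e.g. the output of
#'   [process_core_samples()]).
#' @param tolerance Relative widening of each bound; default 0.10.
#' @return A tibble of violations with columns `row`, `field`, `value`,
#'   `lower`, `upper`; zero rows when everything is in range.
#' @export
validate_derived <- function(derived, tolerance = 0.10) {
  stopifnot(is.data.frame(derived), tolerance >= 0)
  out <- list()
  for (field in names(.derived_ranges)) {
    if (!field %in% names(derived)) next
    rng <- .derived_ranges[[field]]
    lower <- if (rng[1] == 0) 0 else rng[1] * (1 - tolerance)
    upper <- rng[2] * (1 + tolerance)
    x <- derived[[field]]
    bad <- which(!is.na(x) & (x < lower | x > upper))
    if (length(bad) > 0) {
      out[[field]] <- tibble::tibble(row = bad, field = field,
                                     value = x[bad], lower = lower,
                                     upper = upper)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), field = character(),
                          value = numeric(), lower = numeric(),
                          upper = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$field)
}
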