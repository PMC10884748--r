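# Attribute-level implementation of the forest-vegetation-province
# scheme: reclassification of national land-use/vegetation categories
# into seven major forest-vegetation types (plus "Other surfaces"),
# province naming ("<major type> - <floristic province>"), the
# mangrove/wetland exclusion rule, and area tabulation. Polygon geometry
# is an upstream GIS step, out of scope here.

#' The eight reclassification targets
#'
#' Seven major forest-vegetation types plus `"Other surfaces"`, the
#' targets of the 183-category land-use/vegetation reclassification.
#' @format A character vector of length 8.
#' @export
major_forest_types <- c(
  "Coniferous forest",
  "Highland broadleaf forest",
  "Lowland dry forest",
  "Lowland evergreen forest",
  "Mountainous cloud forest",
  "Xerophilous scrub",
  "Mangrove and wetland forest",
  "Other surfaces"
)

#' The 15 mainland floristic provinces
#'
#' Rzedowski's floristic regionalisation of continental Mexico (island
#' provinces excluded), in the English naming used throughout the
#' package.
#' @format A character vector of length 15.
#' @export
floristic_provinces <- c(
  "Baja California",
  "Northwestern Coastal Plain",
  "Western Mountain Range",
  "High Plateau",
  "Northeastern Coastal Plain",
  "Eastern Mountain Range",
  "Pacific Coast",
  "Balsas Depression",
  "Southern Highlands",
  "Gulf Coast",
  "Soconusco",
  "Chiapas Highlands",
  "Tehuacan-Cuicatlan Valley",
  "Yucatan Peninsula",
  "Valley of Mexico"
)

# package-supplied Spanish terms (translations, not the official workbook
# wording)
.major_types_es <- c(
  "Coniferous forest" = "Bosque de coniferas",
  "Highland broadleaf forest" = "Bosque de latifoliadas de altura",
  "Lowland dry forest" = "Bosque seco de tierras bajas",
  "Lowland evergreen forest" = "Bosque perennifolio de tierras bajas",
  "Mountainous cloud forest" = "Bosque mesofilo de montana",
  "Xerophilous scrub" = "Matorral xerofilo",
  "Mangrove and wetland forest" = "Manglar y bosque de humedal",
  "Other surfaces" = "Otras superficies"
)
.provinces_es <- c(
  "Baja California" = "Baja California",
  "Northwestern Coastal Plain" = "Planicie Costera del Noroeste",
  "Western Mountain Range" = "Sierra Madre Occidental",
  "High Plateau" = "Altiplanicie",
  "Northeastern Coastal Plain" = "Planicie Costera del Noreste",
  "Eastern Mountain Range" = "Sierra Madre Oriental",
  "Pacific Coast" = "Costa Pacifica",
  "Balsas Depression" = "Depresion del Balsas",
  "Southern Highlands" = "Serranias Meridionales",
  "Gulf Coast" = "Costa del Golfo de Mexico",
  "Soconusco" = "Soconusco",
  "Chiapas Highlands" = "Altos de Chiapas",
  "Tehuacan-Cuicatlan Valley" = "Valle de Tehuacan-Cuicatlan",
  "Yucatan Peninsula" = "Peninsula de Yucatan",
  "Valley of Mexico" = "Valle de Mexico"
)

#' Load a vegetation-category reclassification table
#'
#' Reads the mapping from national land-use/vegetation categories to the
#' eight reclassification targets. The mapping must be total (every
#' category maps to exactly one target); duplicate categories and unknown
#' targets are schema errors.
#'
#' @param x A CSV path or a data frame with columns `category_name_es`,
#'   `category_name_en`, `major_type` (a three-column unnamed table is
#'   taken in that order).
#' @return A tibble with those three columns.
#' @export
load_category_mapping <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  stopifnot(is.data.frame(x))
  want <- c("category_name_es", "category_name_en", "major_type")
  if (!all(want %in% names(x))) {
    if (ncol(x) < 3) {
      stop("category mapping needs three columns ",
           "(category_name_es, category_name_en, major_type)",
           call. = FALSE)
    }
    names(x)[1:3] <- want
  }
  m <- tibble::as_tibble(x[, want])
  for (col in c("category_name_en", "category_name_es")) {
    if (anyDuplicated(m[[col]])) {
      stop("duplicate category in `", col, "`: ",
           paste(unique(m[[col]][duplicated(m[[col]])]), collapse = ", "),
           call. = FALSE)
    }
  }
  unknown <- setdiff(unique(m$major_type), major_forest_types)
  if (length(unknown) > 0) {
    stop("unknown major-type target(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m
}

#' Compose a forest-vegetation-province name
#'
#' Province names combine the major forest-vegetation type and, after a
#' hyphen, the floristic province, e.g.
#' `"Xerophilous scrub - High Plateau"`. `"Mangrove and wetland forest"`
#' does not form provinces (water dominates its floristic composition)
#' and `"Other surfaces"` is not forest vegetation; both are errors here.
#'
#' @param major_type One of [major_forest_types] (excluding the mangrove
#'   and other-surfaces entries). Vectorised.
#' @param floristic_province One of [floristic_provinces].
#' @param language `"en"` or `"es"` (Spanish terms are package-supplied
#'   translations).
#' @return The hyphen-joined province name(s).
#' @examples
#' make_province_name("Xerophilous scrub", "High Plateau")
#' @export
make_province_name <- function(major_type, floristic_province,
                               language = c("en", "es")) {
  language <- match.arg(language)
  if (any(!major_type %in% major_forest_types)) {
    stop("unknown major forest-vegetation type: ",
         paste(setdiff(major_type, major_forest_types), collapse = ", "),
         call. = FALSE)
  }
  if (any(major_type == "Mangrove and wetland forest")) {
    stop("\"Mangrove and wetland forest\" is excluded from ",
         "forest-vegetation provinces", call. = FALSE)
  }
  if (any(major_type == "Other surfaces")) {
    stop("\"Other surfaces\" does not form forest-vegetation provinces",
         call. = FALSE)
  }
  if (any(!floristic_province %in% floristic_provinces)) {
    stop("unknown floristic province: ",
         paste(setdiff(floristic_province, floristic_provinces),
               collapse = ", "), call. = FALSE)
  }
  if (language == "es") {
    paste(.major_types_es[major_type], .provinces_es[floristic_province],
          sep = " - ")
  } else {
    paste(major_type, floristic_province, sep = " - ")
  }
}

#' Tabulate forest-vegetation-province areas
#'
#' Aggregates `(major_type, floristic_province, area_km2)` tuples (e.g.
#' exported from a GIS intersection) into one record per province:
#' duplicate pairs are summed, mangrove/wetland and other-surfaces
#' records are excluded from province formation but reported in a
#' remainder table so that totals reconcile, and relative areas are
#' expressed as % of the continental area.
#'
#' @param records A data frame with columns `major_type`,
#'   `floristic_province`, `area_km2` (areas >= 0).
#' @param continental_area_km2 Reference continental area; default
#'   1,954,658 km2.
#' @return A list: `provinces` (tibble with `major_type`,
#'   `floristic_province`, `province_name_en`, `province_name_es`,
#'   `area_km2`, `area_pct`), `type_totals` (per-type sums and shares),
#'   `excluded` (tibble of excluded types with summed areas), and
#'   `stats` (`n_provinces`, `total_km2`, `pct_continental`,
#'   `mean_km2`, `median_km2`).
#' @export
tabulate_province_areas <- function(records,
                                    continental_area_km2 = 1954658) {
  stopifnot(is.data.frame(records),
            all(c("major_type", "floristic_province", "area_km2") %in%
                  names(records)),
            continental_area_km2 > 0)
  if (any(!is.finite(records$area_km2)) || any(records$area_km2 < 0)) {
    stop("`area_km2` must be finite and >= 0", call. = FALSE)
  }
  unknown <- setdiff(unique(records$major_type), major_forest_types)
  if (length(unknown) > 0) {
    stop("unknown major forest-vegetation type(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  drop_types <- c("Mangrove and wetland forest", "Other surfaces")
  excluded <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(records, .data$major_type %in% drop_types),
      .data$major_type),
    area_km2 = sum(.data$area_km2), .groups = "drop")

  kept <- dplyr::filter(records, !.data$major_type %in% drop_types)
  prov <- dplyr::summarise(
    dplyr::group_by(kept, .data$major_type, .data$floristic_province),
    area_km2 = sum(.data$area_km2), .groups = "drop")
  prov <- dplyr::mutate(
    prov,
    province_name_en = make_province_name(.data$major_type,
                                          .data$floristic_province, "en"),
    province_name_es = make_province_name(.data$major_type,
                                          .data$floristic_province, "es"),
    area_pct = 100 * .data$area_km2 / continental_area_km2)
  prov <- dplyr::arrange(prov, .data$major_type, .data$floristic_province)
  prov <- prov[, c("major_type", "floristic_province", "province_name_en",
                   "province_name_es", "area_km2", "area_pct")]

  type_totals <- dplyr::summarise(
    dplyr::group_by(prov, .data$major_type),
    n_provinces = dplyr::n(),
    area_km2 = sum(.data$area_km2),
    area_pct = sum(.data$area_pct), .groups = "drop")

  list(provinces = prov,
       type_totals = type_totals,
       excluded = excluded,
       stats = list(
         n_provinces = nrow(prov),
         total_km2 = sum(prov$area_km2),
         pct_continental = 100 * sum(prov$area_km2) / continental_area_km2,
         mean_km2 = if (nrow(prov) > 0) mean(prov$area_km2) else NA_real_,
         median_km2 = if (nrow(prov) > 0) {
           stats::median(prov$area_km2)
         } else NA_real_))
}
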