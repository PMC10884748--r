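# Schemas, readers/writers, validators and summary reports for the two
# inventory tables: the tree site-location table (17 variables) and the
# wood-density table (22 variables, one core sample per tree).

.site_schema <- tibble::tribble(
  ~name,                          ~type,       ~lower,  ~upper,   ~severity,
  "collection_code",              "character", NA,      NA,       NA,
  "species",                      "character", NA,      NA,       NA,
  "author",                       "character", NA,      NA,       NA,
  "genus",                        "character", NA,      NA,       NA,
  "family",                       "character", NA,      NA,       NA,
  "upmid",                        "integer",   1,       311922,   "hard",
  "latitude",                     "numeric",   14,      33,       "hard",
  "longitude",                    "numeric",   -117,    -86,      "hard",
  "elevation_m",                  "numeric",   -50,     4100,     "hard",
  "state",                        "character", NA,      NA,       NA,
  "municipality",                 "character", NA,      NA,       NA,
  "major_forest_vegetation_type", "character", NA,      NA,       NA,
  "floristic_province",           "character", NA,      NA,       NA,
  "collection_date",              "date",      NA,      NA,       NA,
  "taxonomist",                   "character", NA,      NA,       NA,
  "height_m",                     "numeric",   1,       42,       "warn",
  "dbh_cm",                       "numeric",   3,       421,      "warn"
)

.density_extra <- tibble::tribble(
  ~name,              ~type,     ~lower, ~upper, ~severity,
  "basic_density",    "numeric", 0.047,  0.925,  "warn",
  "length_cm",        "numeric", 0.56,   26.99,  "warn",
  "volume_cm3",       "numeric", 0.097,  5.470,  "warn",
  "density_ambient",  "numeric", 0.059,  1.243,  "warn",
  "moisture_pct",     "numeric", 0,      92.5,   "warn"
)

#' Table schema for the inventory datasets
#'
#' Returns the variable schema of one of the two deposited-table layouts:
#' `"sites"` (17 variables, one row per tree) or `"densities"` (22
#' variables, one row per core sample, always one sample per tree). Bounds
#' with severity `"hard"` are physical/encoding limits whose violation
#' flags the row; `"warn"` bounds are ranges observed in the national
#' dataset, widened by 10% at validation time.
#'
#' @param schema `"sites"` or `"densities"`.
#' @return A tibble with columns `name`, `type`, `lower`, `upper`,
#'   `severity`.
#' @export
table_schema <- function(schema = c("sites", "densities")) {
  schema <- match.arg(schema)
  if (schema == "sites") return(.site_schema)
  # densities: Table-2 order, measurement block after the taxonomy block
  dplyr::bind_rows(.site_schema[1:5, ], .density_extra, .site_schema[6:17, ])
}

# header normalisation: lower-case, accent-stripped, alphanumeric only
# (degree signs dropped first: transliteration turns them into digits)
.norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[°ºª]", "", x)
  tr <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  tr[is.na(tr)] <- iconv(x[is.na(tr)], from = "UTF-8", to = "ASCII",
                         sub = "")
  gsub("[^a-z0-9]", "", tr)
}

# alias table: deposited-style (and a few Spanish) headers -> canonical
.header_aliases <- c(
  "collectioncode" = "collection_code",
  "codigodecolecta" = "collection_code",
  "species" = "species", "especie" = "species",
  "author" = "author", "autor" = "author",
  "genus" = "genus", "genero" = "genus",
  "family" = "family", "familia" = "family",
  "upmidsitecode" = "upmid", "upmid" = "upmid",
  "siteslatitude" = "latitude", "latitude" = "latitude",
  "latitud" = "latitude",
  "siteslongitude" = "longitude", "longitude" = "longitude",
  "longitud" = "longitude",
  "elevationm" = "elevation_m", "elevation" = "elevation_m",
  "altitudm" = "elevation_m",
  "state" = "state", "estado" = "state",
  "municipality" = "municipality", "municipio" = "municipality",
  "majorforestvegetationtype" = "major_forest_vegetation_type",
  "floristicprovince" = "floristic_province",
  "provinciafloristica" = "floristic_province",
  "collectiondate" = "collection_date", "fechadecolecta" = "collection_date",
  "taxonomistwhoidentifiedspecies" = "taxonomist",
  "taxonomist" = "taxonomist",
  "reportedheightm" = "height_m", "heightm" = "height_m",
  "reporteddiametercm" = "dbh_cm", "dbhcm" = "dbh_cm",
  "basicwooddensitygcm3" = "basic_density",
  "basicdensity" = "basic_density", "densidadbasicagcm3" = "basic_density",
  "coresamplelengthcm" = "length_cm", "lengthcm" = "length_cm",
  "ellipticcylindervolumecm3" = "volume_cm3", "volumecm3" = "volume_cm3",
  "wooddensityatambienthumiditygcm3" = "density_ambient",
  "densityambient" = "density_ambient",
  "eliminatedmoisture" = "moisture_pct", "moisturepct" = "moisture_pct"
)

.match_headers <- function(headers, schema_tbl) {
  norm <- .norm_header(headers)
  canon <- .header_aliases[norm]
  # canonical names themselves always match
  self <- match(norm, .norm_header(schema_tbl$name))
  canon[is.na(canon)] <- schema_tbl$name[self[is.na(canon)]]
  canon
}

.parse_date <- function(x) {
  out <- as.Date(rep(NA, length(x)))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  dmy <- grepl("^\\d{1,2}[/-]\\d{1,2}[/-]\\d{4}$", x)
  out[dmy] <- as.Date(gsub("-", "/", x[dmy]), format = "%d/%m/%Y")
  out
}

#' Read an inventory table from CSV or XLSX
#'
#' Reads a site-location or wood-density table, matching headers
#' case-insensitively through an alias table (deposited-style English
#' headers, Spanish variants, and the canonical snake-case names all
#' resolve), coercing each variable to its schema type, and validating
#' hard invariants. No row is silently dropped: every parse failure or
#' invariant violation is reported with its row and column in the
#' `violations` attribute, and flagged rows stay in the output.
#'
#' @param path Path to a `.csv` (UTF-8, comma-delimited, header row) or
#'   `.xlsx` file (requires the readxl package).
#' @param schema `"sites"` or `"densities"`.
#' @return A tibble of records with canonical column names (unknown extra
#'   columns preserved as-is), with attribute `"violations"`: a tibble
#'   `(row, column, value, severity, reason)`.
#' @seealso [validate_table()], [write_table()], [dataset_report()]
#' @export
read_table <- function(path, schema = c("sites", "densities")) {
  schema <- match.arg(schema)
  sch <- table_schema(schema)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package; ",
           "export the sheet to CSV instead", call. = FALSE)
    }
    raw <- readxl::read_excel(path, col_types = "text")
    raw <- tibble::as_tibble(raw)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }

  canon <- .match_headers(names(raw), sch)
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  missing_cols <- setdiff(sch$name, names(raw))
  mandatory <- setdiff(sch$name, c("height_m", "dbh_cm"))
  if (length(intersect(missing_cols, mandatory)) > 0) {
    stop("missing mandatory column(s) for schema '", schema, "': ",
         paste(intersect(missing_cols, mandatory), collapse = ", "),
         call. = FALSE)
  }

  violations <- list()
  note <- function(row, column, value, severity, reason) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(row = row, column = column,
                     value = as.character(value),
                     severity = severity, reason = reason)
  }

  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    if (!nm %in% names(raw)) next
    x <- raw[[nm]]
    parsed <- switch(sch$type[i],
      character = as.character(x),
      numeric = suppressWarnings(as.numeric(x)),
      integer = suppressWarnings(as.integer(round(as.numeric(x)))),
      date = .parse_date(as.character(x))
    )
    unparsed <- which(!is.na(x) & x != "" & is.na(parsed))
    if (length(unparsed) > 0) {
      note(unparsed, nm, x[unparsed], "hard", "unparseable cell")
    }
    raw[[nm]] <- parsed
  }

  out <- raw[, c(intersect(sch$name, names(raw)),
                 setdiff(names(raw), sch$name))]
  vio <- if (length(violations) == 0) {
    tibble::tibble(row = integer(), column = character(),
                   value = character(), severity = character(),
                   reason = character())
  } else {
    dplyr::bind_rows(violations)
  }
  vio <- dplyr::bind_rows(vio, validate_table(out, schema))
  attr(out, "violations") <- dplyr::arrange(vio, .data$row, .data$column)
  out
}

#' Validate inventory records against their schema
#'
#' Checks every schema bound (hard limits fail; observed-range limits,
#' widened by `tolerance`, warn) plus the structural invariant that
#' `genus` is the first token of `species`. Validation is total: each
#' record is either accepted (no rows reported) or reported with a reason.
#'
#' @param records A tibble as returned by [read_table()] or built in code.
#' @param schema `"sites"` or `"densities"`.
#' @param tolerance Relative widening applied to observed-range
#'   (`"warn"`) bounds; default 0.10.
#' @return A tibble `(row, column, value, severity, reason)`.
#' @export
validate_table <- function(records, schema = c("sites", "densities"),
                           tolerance = 0.10) {
  schema <- match.arg(schema)
  sch <- table_schema(schema)
  out <- list()
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    if (is.na(sch$severity[i]) || !nm %in% names(records)) next
    lo <- sch$lower[i]
    hi <- sch$upper[i]
    if (sch$severity[i] == "warn") {
      lo <- if (lo == 0) 0 else lo * (1 - tolerance)
      hi <- hi * (1 + tolerance)
    }
    x <- records[[nm]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        row = bad, column = nm, value = as.character(x[bad]),
        severity = sch$severity[i],
        reason = sprintf("outside [%g, %g]", lo, hi))
    }
  }
  if (all(c("genus", "species") %in% names(records))) {
    tok <- sub(" .*$", "", records$species)
    bad <- which(!is.na(records$genus) & !is.na(records$species) &
                   records$genus != tok)
    if (length(bad) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        row = bad, column = "genus",
        value = as.character(records$genus[bad]), severity = "hard",
        reason = "genus is not the first token of species")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), column = character(),
                          value = character(), severity = character(),
                          reason = character()))
  }
  dplyr::bind_rows(out)
}

#' Write an inventory table to CSV
#'
#' UTF-8, comma-delimited, header row with the canonical column names;
#' dates are written in ISO form so that [read_table()] round-trips
#' exactly.
#'
#' @param records A tibble of records.
#' @param path Output `.csv` path.
#' @return `records`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

#' Summarise one column in the style of the dataset documentation
#'
#' For numeric and date columns: count, distinct count, min, max, mean and
#' median (even-length medians interpolate the two central order
#' statistics). For categorical columns: count, distinct count and the
#' top-3 categories with their percentage shares of the non-missing
#' values.
#'
#' @param records A tibble of records.
#' @param column Column name.
#' @param k Number of top categories to report; default 3.
#' @return A one-row tibble with columns `column`, `n`, `n_distinct`,
#'   `min`, `max`, `mean`, `median`, `top_categories` (a formatted
#'   string, `NA` for numeric columns). An empty or all-missing column
#'   yields `n = 0` with `NA` statistics (the empty-summary marker).
#' @examples
#' summarize_column(tibble::tibble(x = c(0.4, 0.5, 0.6)), "x")
#' @export
summarize_column <- function(records, column, k = 3) {
  if (!column %in% names(records)) {
    stop("no column `", column, "` in `records`", call. = FALSE)
  }
  x <- records[[column]]
  x <- x[!is.na(x)]
  empty <- tibble::tibble(column = column, n = length(x),
                          n_distinct = dplyr::n_distinct(x),
                          min = NA_real_, max = NA_real_,
                          mean = NA_real_, median = NA_real_,
                          top_categories = NA_character_)
  if (length(x) == 0) return(empty)
  if (is.numeric(x) || inherits(x, "Date")) {
    empty$min <- as.numeric(min(x))
    empty$max <- as.numeric(max(x))
    empty$mean <- as.numeric(mean(x))
    empty$median <- as.numeric(stats::median(x))
  } else {
    tab <- sort(table(x), decreasing = TRUE)
    top <- utils::head(tab, k)
    empty$top_categories <- paste(
      sprintf("%s (%.1f%%)", names(top), 100 * as.numeric(top) / length(x)),
      collapse = "; ")
  }
  empty
}

#' Full summary report for an inventory table
#'
#' One [summarize_column()] row per schema variable present, plus
#' dataset-level counts: number of records, distinct species, distinct
#' sites, and the mean/median number of trees per site.
#'
#' @param records A tibble of records.
#' @param schema `"sites"` or `"densities"`.
#' @return A list with elements `columns` (tibble of per-column
#'   summaries) and `dataset` (named list of counts).
#' @export
dataset_report <- function(records, schema = c("sites", "densities")) {
  schema <- match.arg(schema)
  if (nrow(records) == 0) {
    stop("`records` is empty; nothing to report", call. = FALSE)
  }
  sch <- table_schema(schema)
  vars <- intersect(sch$name, names(records))
  columns <- dplyr::bind_rows(lapply(vars, function(v) {
    summarize_column(records, v)
  }))
  per_site <- if ("upmid" %in% names(records)) {
    as.numeric(table(records$upmid))
  } else {
    numeric(0)
  }
  dataset <- list(
    n_records = nrow(records),
    n_species = if ("species" %in% names(records)) {
      dplyr::n_distinct(records$species[!is.na(records$species)])
    } else NA_integer_,
    n_sites = if (length(per_site) > 0) length(per_site) else NA_integer_,
    trees_per_site_mean = if (length(per_site) > 0) mean(per_site) else NA_real_,
    trees_per_site_median = if (length(per_site) > 0) {
      stats::median(per_site)
    } else NA_real_
  )
  list(columns = columns, dataset = dataset)
}
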