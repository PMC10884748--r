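test_that("write/read roundtrip is the identity on synthetic tables", {
  cfg <- synthetic_config(n_species = 40, n_sites = 60, seed = 21)
  sites <- generate_site_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(sites, path)
  back <- read_table(path, "sites")
  expect_equal(nrow(attr(back, "violations")), 0)
  attr(back, "violations") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(sites))

  dens <- generate_core_dataset(synthetic_config(n_species = 30, seed = 22))$records
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_table(dens, path2)
  back2 <- read_table(path2, "densities")
  attr(back2, "violations") <- NULL
  expect_equal(as.data.frame(back2), as.data.frame(dens))
})

test_that("deposited-style and Spanish headers resolve to canonical names", {
  cfg <- synthetic_config(n_species = 10, n_sites = 10, seed = 3)
  sites <- utils::head(generate_site_dataset(cfg), 5)
  renamed <- sites
  names(renamed) <- c("Collection code", "Especie", "Author", "Género",
                      "Familia", "UPMID site code", "Site's latitude (°)",
                      "Site's longitude (°)", "Elevation (m)", "Estado",
                      "Municipio", "Major forest-vegetation type",
                      "Floristic province", "Collection date",
                      "Taxonomist who identified species",
                      "Reported height (m)", "Reported diameter (cm)")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path)
  back <- read_table(path, "sites")
  expect_setequal(names(back), names(sites))
  expect_equal(back$latitude, sites$latitude)
  expect_equal(back$species, sites$species)
})

test_that("violations are reported with coordinates and rows are kept", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- synthetic_config(n_species = 5, n_sites = 5, seed = 9)
  sites <- utils::head(generate_site_dataset(cfg), 3)
  sites$latitude[2] <- 50          # off the continental grid
  sites$genus[3] <- "Wronggenus"   # breaks genus == first token of species
  write_table(sites, path)
  back <- read_table(path, "sites")
  vio <- attr(back, "violations")
  expect_equal(nrow(back), 3)
  expect_true(any(vio$row == 2 & vio$column == "latitude"))
  expect_true(any(vio$row == 3 & vio$column == "genus"))
  expect_true(all(vio$severity == "hard"))
})

test_that("unparseable cells and missing mandatory columns are schema errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- synthetic_config(n_species = 5, n_sites = 5, seed = 9)
  sites <- utils::head(generate_site_dataset(cfg), 3)
  raw <- sites
  raw$elevation_m <- as.character(raw$elevation_m)
  raw$elevation_m[1] <- "not-a-number"
  readr::write_csv(raw, path)
  back <- read_table(path, "sites")
  vio <- attr(back, "violations")
  expect_true(any(vio$row == 1 & vio$column == "elevation_m" &
                    vio$reason == "unparseable cell"))
  expect_true(is.na(back$elevation_m[1]))

  readr::write_csv(sites[, setdiff(names(sites), "species")], path)
  expect_error(read_table(path, "sites"), "mandatory")
})

test_that("column summaries follow the documented reporting style", {
  expect_equal(summarize_column(tibble::tibble(x = c(0.4, 0.5, 0.6)), "x")$mean, 0.5)
  expect_equal(summarize_column(tibble::tibble(x = c(0.4, 0.5, 0.6)), "x")$median, 0.5)
  expect_equal(summarize_column(tibble::tibble(x = c(1, 2, 3, 4)), "x")$median, 2.5)
  s <- summarize_column(tibble::tibble(k = c("a", "a", "b", "c")), "k")
  expect_equal(s$n, 4)
  expect_equal(s$n_distinct, 3)
  expect_match(s$top_categories, "^a \\(50\\.0%\\)")
  empty <- summarize_column(tibble::tibble(x = NA_real_), "x")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))
  expect_error(summarize_column(tibble::tibble(x = 1), "y"), "no column")
})

test_that("dataset report covers every schema variable and site-level counts", {
  g <- generate_core_dataset(synthetic_config(n_species = 40, seed = 5))
  rep <- dataset_report(g$records, "densities")
  expect_equal(nrow(rep$columns), 22)
  expect_equal(rep$dataset$n_records, nrow(g$records))
  expect_equal(rep$dataset$n_species,
               length(unique(g$records$species)))
  expect_equal(rep$dataset$n_sites, length(unique(g$records$upmid)))
  # order invariance
  perm <- g$records[sample.int(nrow(g$records)), ]
  rep2 <- dataset_report(perm, "densities")
  expect_equal(dplyr::arrange(rep$columns, column),
               dplyr::arrange(rep2$columns, column))
  # single record: distinct counts all 1
  rep1 <- dataset_report(g$records[1, ], "densities")
  expect_true(all(rep1$columns$n_distinct <= 1))
  expect_error(dataset_report(g$records[0, ], "densities"), "empty")
})
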