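write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_occurrences preserves rows, propagates missingness, flags spans", {
  p <- write_csv_fixture(c("taxon,mountain,elev",
                           "Quercus fabri,GS,120",
                           "Pinus massoniana,GS,",
                           "Ilex cornuta,GS,-50"))
  cm <- list(taxon = "taxon", mountain = "mountain", elevation = "elev")
  recs <- read_occurrences(p, column_map = cm)
  expect_equal(nrow(recs), 3L)
  expect_true(is.na(recs$elevation_m[2]))
  expect_equal(recs$elevation_m[1], 120)

  flagged <- read_occurrences(p, column_map = cm,
                              spans = list(GS = c(100, 1480)))
  expect_equal(flagged$out_of_span, c(FALSE, FALSE, TRUE))

  expect_error(read_occurrences(p, column_map = list(taxon = "taxon",
                                                     mountain = "mountain",
                                                     elevation = "altitude")),
               "required column")
})

test_that("tab-delimited files are auto-detected", {
  p <- write_csv_fixture(c("taxon\tmountain\televation",
                           "Quercus fabri\tGS\t120"))
  recs <- read_occurrences(p)
  expect_equal(recs$taxon_name, "Quercus fabri")
  expect_equal(recs$elevation_m, 120)
})

test_that("cleaning removes each hazard class and reports the identity", {
  recs <- tibble::tibble(
    taxon_name = c("Quercus fabrii", "Quercus fabri", "Quercus fabri",
                   "Pinus massoniana", "Mystery plant"),
    mountain_id = "GS",
    elevation_m = c(120.2, 120.4, NA, 300, 5000))
  syn <- tibble::tibble(raw_name = "Quercus fabrii",
                        accepted_name = "Quercus fabri")
  tax <- tibble::tibble(accepted_name = c("Quercus fabri", "Pinus massoniana"),
                        genus = c("Quercus", "Pinus"),
                        family = c("Fagaceae", "Pinaceae"))
  out <- clean_occurrences(recs, synonyms = syn, taxonomy = tax,
                           spans = list(GS = c(0, 1480)))
  rep <- out$report
  # synonym maps row 1 onto row 2 (both round to 120 m) -> one duplicate
  expect_equal(rep$duplicates, 1L)
  expect_equal(rep$no_elevation, 1L)
  expect_equal(rep$out_of_span, 1L)
  expect_equal(rep$unresolved_dropped, 0L)
  expect_equal(rep$n_in - (rep$no_elevation + rep$out_of_span +
                             rep$duplicates + rep$unresolved_dropped),
               rep$n_out)
  expect_setequal(out$records$taxon_name, c("Quercus fabri", "Pinus massoniana"))

  dropped <- clean_occurrences(recs, synonyms = syn, taxonomy = tax,
                               spans = list(GS = c(0, 1480)),
                               drop_unresolved = TRUE)
  expect_equal(dropped$report$unresolved_dropped, 0L) # Mystery was out-of-span
  recs2 <- dplyr::mutate(recs, elevation_m = replace(elevation_m, 5, 400))
  dropped2 <- clean_occurrences(recs2, synonyms = syn, taxonomy = tax,
                                drop_unresolved = TRUE)
  expect_equal(dropped2$report$unresolved_dropped, 1L)
  expect_equal(dropped2$report$unresolved_names, "Mystery plant")
})

test_that("cleaning is idempotent and never edits mountain or elevation", {
  withr::with_seed(42, {
    recs <- tibble::tibble(
      taxon_name = sample(c("a spp", "b spp", "c spp", "d spp"), 60, TRUE),
      mountain_id = sample(c("M1", "M2"), 60, TRUE),
      elevation_m = replace(runif(60, 0, 900), sample(60, 6), NA))
  })
  syn <- tibble::tibble(raw_name = "a spp", accepted_name = "alpha spp")
  once <- clean_occurrences(recs, synonyms = syn)
  twice <- clean_occurrences(once$records, synonyms = syn)
  expect_identical(twice$records, once$records)
  expect_equal(twice$report$no_elevation + twice$report$duplicates, 0L)
  # synonym mapping left every surviving row's mountain/elevation untouched
  key_in <- paste(recs$mountain_id, recs$elevation_m)
  key_out <- paste(once$records$mountain_id, once$records$elevation_m)
  expect_true(all(key_out %in% key_in))
})

test_that("degenerate cleans fail loudly", {
  recs <- tibble::tibble(taxon_name = "x", mountain_id = "M",
                         elevation_m = NA_real_)
  expect_error(clean_occurrences(recs), "no usable records")
  chained <- tibble::tibble(raw_name = c("a", "b"), accepted_name = c("b", "c"))
  expect_error(clean_occurrences(
    tibble::tibble(taxon_name = "a", mountain_id = "M", elevation_m = 1),
    synonyms = chained), "acyclic")
})

test_that("native status is a pure function of the accepted name", {
  recs <- tibble::tibble(taxon_name = c("a", "b", "c", "a"),
                         mountain_id = "M", elevation_m = 1:4)
  expect_true(all(tag_native_status(recs)$native_status == "native"))
  tagged <- tag_native_status(recs, alien_list = c("a", "ghost species"))
  expect_equal(tagged$native_status, c("non_native", "native", "native",
                                       "non_native"))
  expect_false("ghost species" %in% tagged$taxon_name)
})
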