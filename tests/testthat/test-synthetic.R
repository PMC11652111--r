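test_that("Yule trees are reproducible, ultrametric and sized correctly", {
  t1 <- simulate_tree(5, seed = 101)
  expect_equal(ape::Ntip(t1), 5L)
  expect_identical(ape::write.tree(t1),
                   ape::write.tree(simulate_tree(5, seed = 101)))
  depths <- ape::node.depth.edgelength(t1)[1:5]
  expect_lt(diff(range(depths)), 1e-9) # ultrametric
  expect_true(all(t1$edge.length > 0))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("ranges respect the span and scenario constraints", {
  cfg <- scenario_config(n_species = 60, seed = 7, scenario = "filter_high")
  tree <- simulate_tree(60, seed = 7)
  ranges <- simulate_ranges(tree, cfg)
  expect_true(all(ranges$lo >= cfg$min_elev & ranges$hi <= cfg$max_elev))
  expect_true(all(ranges$hi >= ranges$lo))
  clade <- attr(ranges, "filtered_clade")
  expect_gte(length(clade), 12L) # >= 20% of tips
  span <- cfg$max_elev - cfg$min_elev
  expect_true(all(ranges$lo[ranges$taxon %in% clade] >=
                    cfg$min_elev + 2 / 3 * span - 1e-9))

  cfg_low <- scenario_config(n_species = 60, seed = 8, scenario = "filter_low")
  rl <- simulate_ranges(tree, cfg_low)
  clade_l <- attr(rl, "filtered_clade")
  expect_true(all(rl$hi[rl$taxon %in% clade_l] <=
                    cfg$min_elev + span / 3 + 1e-9))
})

test_that("monotonic decrease yields belt richness falling with elevation", {
  cfg <- scenario_config(n_species = 500, seed = 12,
                         scenario = "monotonic_decrease")
  tree <- simulate_tree(500, seed = 12)
  ranges <- simulate_ranges(tree, cfg)
  bm <- matrix_from_ranges(ranges, cfg)
  sr <- rowSums(bm$presence)
  expect_lt(suppressWarnings(
    cor(sr, seq_along(sr), method = "spearman")), 0)
  expect_true(all(diff(sr) <= 0)) # base-anchored attrition: non-increasing
})

test_that("occurrence simulation reproduces the stated cleaning hazards", {
  tree <- simulate_tree(80, seed = 21)
  clean_cfg <- scenario_config(n_species = 80, seed = 21,
                               duplicate_rate = 0, missing_elevation_rate = 0,
                               elevation_noise_sd_m = 0)
  ranges <- simulate_ranges(tree, clean_cfg)
  occ <- simulate_occurrences(ranges, clean_cfg)
  out <- clean_occurrences(dplyr::rename(occ$occurrences,
                                         taxon_name = taxon,
                                         mountain_id = mountain,
                                         elevation_m = elevation))
  expect_equal(out$report$no_elevation, 0L)
  # no rows were injected: the only "duplicates" the cleaner may collapse
  # are chance metre-rounding collisions, counted here independently
  collisions <- sum(duplicated(paste(occ$occurrences$taxon,
                                     round(occ$occurrences$elevation))))
  expect_equal(out$report$duplicates, collisions)

  # missing_rate = 1 blanks everything: cleaner must refuse
  all_missing <- scenario_config(n_species = 10, seed = 4,
                                 missing_elevation_rate = 1)
  r2 <- simulate_ranges(simulate_tree(10, seed = 4), all_missing)
  occ2 <- simulate_occurrences(r2, all_missing)
  expect_true(all(is.na(occ2$occurrences$elevation)))
  expect_error(clean_occurrences(dplyr::rename(occ2$occurrences,
                                               taxon_name = taxon,
                                               mountain_id = mountain,
                                               elevation_m = elevation)),
               "no usable records")

  # injected duplicate fraction tracks the configured rate (binomial check)
  dup_cfg <- scenario_config(n_species = 300, seed = 33, duplicate_rate = 0.2,
                             missing_elevation_rate = 0,
                             elevation_noise_sd_m = 0)
  r3 <- simulate_ranges(simulate_tree(300, seed = 33), dup_cfg)
  occ3 <- simulate_occurrences(r3, dup_cfg)
  out3 <- clean_occurrences(dplyr::rename(occ3$occurrences,
                                          taxon_name = taxon,
                                          mountain_id = mountain,
                                          elevation_m = elevation))
  n_tot <- nrow(occ3$occurrences)
  frac <- out3$report$duplicates / n_tot
  se <- sqrt(0.2 * 0.8 / n_tot)
  expect_lt(abs(frac - 0.2), 3 * se + 0.01) # small slack: key collisions
})

test_that("range-through occupancy is recovered exactly at zero noise", {
  cfg <- scenario_config(n_species = 40, seed = 55, elevation_noise_sd_m = 0,
                         duplicate_rate = 0.3, missing_elevation_rate = 0.4)
  tree <- simulate_tree(40, seed = 55)
  ranges <- simulate_ranges(tree, cfg)
  occ <- simulate_occurrences(ranges, cfg)
  cleaned <- clean_occurrences(dplyr::rename(occ$occurrences,
                                             taxon_name = taxon,
                                             mountain_id = mountain,
                                             elevation_m = elevation))
  bm <- assign_belts(cleaned$records, occ$truth$grid, mode = "range_through")
  for (sp in bm$taxa) {
    expect_equal(unname(which(bm$presence[, sp] == 1L)),
                 occ$truth$belt_presence[[sp]])
  }
  expect_setequal(bm$taxa, ranges$taxon)
})

test_that("belt-area profiles have the promised shapes", {
  g <- build_grid("m", 0, 2000, 100)
  hump <- simulate_belt_areas(g, "hump", seed = 2)
  expect_true(all(hump$area_km2 > 0))
  am <- which.max(hump$area_km2)
  expect_gte(am, ceiling(nrow(g) / 3))
  expect_lte(am, floor(2 * nrow(g) / 3))
  mono <- simulate_belt_areas(g, "monotone", seed = 2)
  expect_true(all(diff(mono$area_km2) < 0))
  expect_true(all(mono$area_km2 > 0))
})

test_that("non-native assignment couples belt richness when asked", {
  tree <- simulate_tree(150, seed = 61)
  cfg <- scenario_config(n_species = 150, seed = 61, nonnative_fraction = 0.2,
                         nonnative_coupling = 1)
  ranges <- simulate_ranges(tree, cfg)
  zero <- assign_nonnatives(tree, ranges,
                            scenario_config(n_species = 150, seed = 61,
                                            nonnative_fraction = 0))
  expect_true(all(zero$status$native_status == "native"))
  expect_identical(zero$ranges, ranges)
  nn <- assign_nonnatives(tree, ranges, cfg)
  expect_equal(sum(nn$status$native_status == "non_native"), 30L)
  bm <- matrix_from_ranges(nn$ranges, cfg)
  r_coupled <- native_nonnative_correlation(bm, nn$status)$r
  expect_gt(r_coupled, 0)

  # coupling 0: mean correlation across replicates is centred on zero
  rs <- purrr::map_dbl(1:100, function(i) {
    cfg_i <- scenario_config(n_species = 60, seed = 7000 + i,
                             nonnative_fraction = 0.25,
                             nonnative_coupling = 0)
    tr <- simulate_tree(60, seed = 7000 + i)
    rg <- simulate_ranges(tr, cfg_i)
    nn_i <- assign_nonnatives(tr, rg, cfg_i)
    out <- native_nonnative_correlation(matrix_from_ranges(nn_i$ranges, cfg_i),
                                        nn_i$status)
    out$r
  })
  rs <- rs[is.finite(rs)]
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})
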