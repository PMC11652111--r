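test_that("quasi-Poisson fit agrees with an independent Fisher-scoring oracle", {
  x <- 0:8
  y <- round(exp(1 + 0.5 * x))
  fit <- fit_quasipoisson(x, y)
  beta <- unname(oracle_irls_quasipois(x, y))
  expect_equal(fit$slope, beta[2], tolerance = 1e-6)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-6)
  expect_lt(abs(fit$slope - 0.5), 0.02) # noiseless log-linear recovery
  expect_gt(fit$pseudo_r2, 0.99)
})

test_that("degenerate responses are handled per contract", {
  expect_error(fit_quasipoisson(1:2, c(1, 2)), "at least 3")
  expect_error(fit_quasipoisson(1:5, rep(0, 5)), "all responses are zero")
  fit0 <- fit_quasipoisson(1:6, rep(4, 6))
  expect_equal(fit0$slope, 0, tolerance = 1e-10)
  expect_equal(fit0$pseudo_r2, 0, tolerance = 1e-10)
  expect_warning(fit_quasipoisson(1:5, c(1.5, 2.2, 3.3, 4.1, 5.9)),
                 "non-integer")
})

test_that("log link: scaling counts moves the intercept, not the slope", {
  withr::with_seed(3, {
    x <- runif(40, 0, 3)
    y <- rpois(40, exp(1 + 0.4 * x))
  })
  y <- y + 1 # avoid zeros after scaling checks
  f1 <- fit_quasipoisson(x, y)
  f7 <- fit_quasipoisson(x, 7 * y)
  expect_equal(f7$slope, f1$slope, tolerance = 1e-8)
  expect_equal(f7$intercept - f1$intercept, log(7), tolerance = 1e-8)
})

test_that("simulation recovery: slope estimates are unbiased at modest n", {
  withr::with_seed(29, {
    slopes <- purrr::map_dbl(1:60, function(i) {
      x <- runif(50, 0, 4)
      y <- rpois(50, exp(2 + 0.3 * x)) # belt-richness-scale counts
      fit_quasipoisson(x, y)$slope
    })
  })
  expect_lt(abs(mean(slopes) - 0.3), 2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("richness-area fit needs areas and finds a constructed effect", {
  bm <- toy_matrix()
  prof <- belt_richness(bm)
  expect_error(richness_area_fit(prof), "areas not attached")
  withr::with_seed(41, {
    area <- exp(runif(12, 0, 3))
    sr <- rpois(12, 5 * area)
  })
  prof2 <- tibble::tibble(sr = sr, area_km2 = area)
  fit <- richness_area_fit(prof2)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
  expect_error(richness_area_fit(prof2[1, ]), "at least 3")
})

test_that("native/non-native correlation handles proportional and flat inputs", {
  g <- build_grid("m", 0, 400, 100)
  # native richness 4,3,2,1 with one non-native tracking every belt
  taxa <- c(paste0("n", 1:4), "alien1")
  recs <- purrr::map_dfr(1:4, function(b) {
    tibble::tibble(taxon_name = c(paste0("n", seq_len(5 - b)), "alien1"),
                   mountain_id = "m", elevation_m = (b - 1) * 100 + 50)
  })
  bm <- assign_belts(recs, g)
  status <- tibble::tibble(taxon = taxa,
                           native_status = c(rep("native", 4), "non_native"))
  out <- native_nonnative_correlation(bm, status)
  expect_equal(out$flag, "zero_variance") # non-native SR constant at 1
  expect_true(is.na(out$r))

  # non-native richness exactly proportional to native richness
  recs2 <- purrr::map_dfr(1:4, function(b) {
    k <- 5 - b
    tibble::tibble(taxon_name = c(paste0("n", seq_len(k)),
                                  paste0("a", seq_len(k))),
                   mountain_id = "m", elevation_m = (b - 1) * 100 + 50)
  })
  status2 <- tibble::tibble(taxon = c(paste0("n", 1:4), paste0("a", 1:4)),
                            native_status = rep(c("native", "non_native"),
                                                each = 4))
  out2 <- native_nonnative_correlation(assign_belts(recs2, g), status2)
  expect_equal(out2$r, 1)
  expect_equal(out2$n, 4L)
})

test_that("NRI trends classify slope sign at alpha = 0.05", {
  prof <- tibble::tibble(midpoint = seq(50, 950, by = 100),
                         nri = 2 - 0.002 * seq(50, 950, by = 100),
                         evaluable = TRUE)
  fit <- suppressWarnings(nri_trend(prof)) # perfect fit warns in summary.lm
  expect_equal(fit$slope, -0.002, tolerance = 1e-12) # noiseless line, exact
  expect_equal(fit$trend, "clustering_decreasing")
  expect_equal(fit$pseudo_r2, 1)
  expect_error(nri_trend(prof[1:2, ]), "at least 3")

  withr::with_seed(13, {
    flat_frac <- mean(purrr::map_lgl(1:40, function(i) {
      noise <- tibble::tibble(midpoint = prof$midpoint,
                              nri = sample(rnorm(10)), evaluable = TRUE)
      nri_trend(noise)$trend == "flat"
    }))
  })
  expect_gte(flat_frac, 0.9) # shuffled NRI rarely yields significance
})

test_that("peak elevation uses the max-SR belt midpoint with low-tie rule", {
  prof <- tibble::tibble(midpoint = c(50, 150, 250, 350),
                         sr = c(9, 12, 12, 3))
  expect_equal(peak_elevation(prof), 150) # tie -> lower belt
  expect_equal(peak_elevation(dplyr::mutate(prof, sr = sr + 100)),
               150) # invariant to adding a constant
  mono <- tibble::tibble(midpoint = c(50, 150, 250), sr = c(30, 20, 10))
  expect_equal(peak_elevation(mono), 50)
  prof550 <- tibble::tibble(midpoint = c(450, 550, 650), sr = c(5, 11, 7))
  expect_equal(peak_elevation(prof550), 550)
})

test_that("peak determinants fit each attribute and demand 4+ mountains", {
  atts <- tibble::tibble(mountain_id = paste0("M", 1:8),
                         relative_elevation_m = c(1250, 1374, 2000, 1808,
                                                  2706, 2151, 2020, 1862),
                         longitude_deg = runif(8, 108, 118),
                         amt_c = runif(8, 10, 18), ap_mm = runif(8, 1200, 2000))
  peaks <- tibble::tibble(mountain_id = atts$mountain_id,
                          peak_m = 0.5 * atts$relative_elevation_m)
  fits <- suppressWarnings(peak_determinants(peaks, atts, family = "gaussian"))
  expect_equal(nrow(fits), 4L)
  rel <- dplyr::filter(fits, predictor == "relative_elevation_m")
  expect_equal(rel$pseudo_r2, 1, tolerance = 1e-9)
  expect_equal(rel$slope, 0.5, tolerance = 1e-9)
  expect_equal(unique(fits$p_adjusted), "none")
  expect_error(peak_determinants(peaks[1:3, ], atts), "at least 4")

  # permuting an attribute against the peaks destroys its explanatory power
  withr::with_seed(19, {
    r2s <- purrr::map_dbl(1:30, function(i) {
      sh <- atts
      sh$relative_elevation_m <- sample(sh$relative_elevation_m)
      f <- suppressWarnings(peak_determinants(peaks, sh, family = "gaussian"))
      dplyr::filter(f, predictor == "relative_elevation_m")$pseudo_r2
    })
  })
  expect_lt(mean(r2s), 0.4)
})

test_that("tidy and glance return broom-shaped tibbles", {
  fit <- fit_quasipoisson(0:8, round(exp(1 + 0.5 * (0:8))),
                          response = "sr", predictor = "area")
  td <- tidy(fit)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("response", "predictor", "family", "slope", "pseudo_r2",
                     "pearson_r2", "p_value", "n"))
  gl <- glance(fit)
  expect_true(all(c("dispersion", "deviance", "null_deviance") %in% names(gl)))
})
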