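#' Scenario configuration for the synthetic mountain generator
#'
#' The defaults describe a realistic subtropical mountain flora at desk
#' scale: 200 species over a 0-2000 m span, about 10 records per species
#' (herbarium datasets in this region carry roughly 5-17 records per
#' species), 20 m of elevation noise (typical altimeter/plot-interval
#' error), 10% duplicate rows and 5% records without elevation (the two
#' cleaning hazards the pipeline must survive), and a 5% non-native
#' fraction (regional alien floras run 2-6% of species) whose belt richness
#' covaries strongly with native richness (`nonnative_coupling = 0.8`).
#'
#' Scenarios shape the expected richness gradient: `neutral` places range
#' midpoints uniformly (mid-domain constraint only); `filter_low` /
#' `filter_high` confine one clade (>= 20% of tips) to the bottom / top
#' third of the span, emulating habitat filtering and hence expected
#' phylogenetic clustering there; `mid_peak` concentrates midpoints
#' mid-slope (hump-shaped richness); `monotonic_decrease` anchors every
#' range at the mountain base with lognormal widths (nested attrition), so
#' expected richness declines monotonically and the peak sits in the lowest
#' belt.
#'
#' @param n_species Number of species (>= 4).
#' @param min_elev,max_elev Mountain span in metres.
#' @param scenario One of `"neutral"`, `"filter_low"`, `"filter_high"`,
#'   `"mid_peak"`, `"monotonic_decrease"`.
#' @param records_per_species Mean records per species (Poisson).
#' @param elevation_noise_sd_m Gaussian noise sd added to record elevations.
#' @param duplicate_rate Target fraction of duplicate rows in the emitted
#'   occurrence table.
#' @param missing_elevation_rate Probability that a (non range-endpoint)
#'   record's elevation is blanked; 1 blanks everything.
#' @param nonnative_fraction Fraction of species labelled non-native
#'   (< 0.5).
#' @param nonnative_coupling In `[0, 1]`: 0 labels species uniformly at
#'   random, 1 prefers species whose ranges overlap richness-dense
#'   elevations.
#' @param belt_width_m Belt width used for the truth record's occupancy.
#' @param seed Integer seed; all generator randomness flows through it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_species = 200, min_elev = 0, max_elev = 2000,
                            scenario = c("neutral", "filter_low", "filter_high",
                                         "mid_peak", "monotonic_decrease"),
                            records_per_species = 10,
                            elevation_noise_sd_m = 20,
                            duplicate_rate = 0.1,
                            missing_elevation_rate = 0.05,
                            nonnative_fraction = 0.05,
                            nonnative_coupling = 0.8,
                            belt_width_m = 100,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (n_species < 4) abort("n_species must be at least 4")
  if (max_elev <= min_elev) abort("max_elev must exceed min_elev")
  rates <- c(duplicate_rate, missing_elevation_rate, nonnative_fraction,
             nonnative_coupling)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (nonnative_fraction >= 0.5) abort("nonnative_fraction must be < 0.5")
  structure(list(n_species = as.integer(n_species), min_elev = min_elev,
                 max_elev = max_elev, scenario = scenario,
                 records_per_species = records_per_species,
                 elevation_noise_sd_m = elevation_noise_sd_m,
                 duplicate_rate = duplicate_rate,
                 missing_elevation_rate = missing_elevation_rate,
                 nonnative_fraction = nonnative_fraction,
                 nonnative_coupling = nonnative_coupling,
                 belt_width_m = belt_width_m, seed = seed),
            class = "scenario_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (constant-speciation, no-extinction) tree: ultrametric with strictly
#' positive branch lengths, tips labelled `sp001`, `sp002`, ... A single
#' birth rate suffices because every downstream statistic consumes only
#' tree shape and branch lengths.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 2) abort("need at least 2 species")
  res <- with_seed_reported(seed, {
    ape::rphylo(n_species, birth = 1, death = 0)
  })
  tree <- res$value
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# Lognormal range widths, clipped to at most `max_width`.
draw_widths <- function(n, span, max_width = span, meanlog = log(0.3 * span),
                        sdlog = 0.6) {
  pmin(rlnorm(n, meanlog, sdlog), max_width)
}

# Internal nodes whose clades hold between lo_frac and hi_frac of the tips.
candidate_clades <- function(tree, lo_frac = 0.2, hi_frac = 0.6) {
  n_tip <- ape::Ntip(tree)
  sizes <- vapply((n_tip + 1):(n_tip + tree$Nnode), function(nd) {
    length(phangorn_free_descendants(tree, nd))
  }, integer(1))
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  lo <- ceiling(lo_frac * n_tip)
  ok <- sizes >= lo & sizes <= floor(hi_frac * n_tip)
  if (!any(ok)) ok <- sizes >= lo & nodes != n_tip + 1L  # allow big clades, not root
  nodes[ok]
}

# Tip indices descending from an internal node (no phangorn dependency).
phangorn_free_descendants <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Simulate per-species elevational ranges on a phylogeny
#'
#' See [scenario_config()] for what each scenario encodes. All ranges are
#' clipped to the mountain span; under `filter_high` every tip of the
#' chosen clade has its lower limit at or above the top third of the span
#' (symmetrically for `filter_low`).
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param config A [scenario_config()].
#' @return Tibble `(taxon, lo, hi)` with an attribute `filtered_clade`
#'   (tip labels of the confined clade, or `NULL`).
#' @export
simulate_ranges <- function(tree, config) {
  span <- config$max_elev - config$min_elev
  n <- ape::Ntip(tree)
  res <- with_seed_reported(config$seed, {
    taxa <- tree$tip.label
    clade_tips <- NULL
    if (config$scenario %in% c("filter_low", "filter_high")) {
      cand <- candidate_clades(tree)
      if (!length(cand)) abort("no clade with >= 20% of tips available")
      node <- if (length(cand) == 1L) cand else sample(cand, 1)
      clade_tips <- taxa[phangorn_free_descendants(tree, node)]
    }
    lo <- hi <- numeric(n)
    for (i in seq_len(n)) {
      confined <- !is.null(clade_tips) && taxa[i] %in% clade_tips
      if (confined) {
        third <- span / 3
        w <- draw_widths(1, span, max_width = third,
                         meanlog = log(0.4 * third))
        base <- if (config$scenario == "filter_high")
          config$min_elev + 2 * third else config$min_elev
        start <- base + runif(1, 0, third - w)
        lo[i] <- start; hi[i] <- start + w
      } else if (config$scenario == "monotonic_decrease") {
        w <- draw_widths(1, span, meanlog = log(0.3 * span), sdlog = 0.8)
        lo[i] <- config$min_elev; hi[i] <- config$min_elev + w
      } else {
        mid <- switch(config$scenario,
          mid_peak = config$min_elev + span * rbeta(1, 2.5, 2.5),
          config$min_elev + runif(1, 0, span))
        w <- draw_widths(1, span)
        lo[i] <- max(config$min_elev, mid - w / 2)
        hi[i] <- min(config$max_elev, mid + w / 2)
      }
    }
    list(ranges = tibble::tibble(taxon = taxa, lo = lo, hi = hi),
         clade = clade_tips)
  })
  structure(res$value$ranges, filtered_clade = res$value$clade)
}

#' Simulate raw occurrence records with cleaning hazards
#'
#' Each species receives records at its two range endpoints plus a
#' Poisson-distributed number of uniform interior elevations; Gaussian
#' noise (`elevation_noise_sd_m`) is added and clipped to the span.
#' Duplicate rows are appended so their share of the emitted table is about
#' `duplicate_rate`, and elevations of non-endpoint records are blanked
#' with probability `missing_elevation_rate` (rate 1 blanks everything,
#' endpoints included). The endpoint records guarantee that, at zero noise,
#' range-through belt occupancy is exactly recoverable after cleaning.
#'
#' @param ranges Tibble from [simulate_ranges()].
#' @param config A [scenario_config()].
#' @param mountain_id Mountain label for the records.
#' @return List: `occurrences` (tibble `taxon`, `mountain`, `elevation`,
#'   `source`) and `truth` (intended ranges, per-belt presence under
#'   range-through on the config grid, the grid, seed and config echo).
#' @export
simulate_occurrences <- function(ranges, config, mountain_id = "synthetic") {
  res <- with_seed_reported(config$seed, {
    rows <- purrr::pmap_dfr(ranges, function(taxon, lo, hi) {
      n_extra <- rpois(1, max(config$records_per_species - 2, 0))
      elev <- c(lo, hi, runif(n_extra, lo, hi))
      endpoint <- c(TRUE, TRUE, rep(FALSE, n_extra))
      if (config$elevation_noise_sd_m > 0) {
        elev <- elev + rnorm(length(elev), 0, config$elevation_noise_sd_m)
        elev <- pmin(pmax(elev, config$min_elev), config$max_elev)
      }
      tibble::tibble(taxon = taxon, elevation = elev, endpoint = endpoint)
    })
    n0 <- nrow(rows)
    if (config$duplicate_rate > 0 && config$duplicate_rate < 1) {
      n_dup <- rbinom(1, n0, config$duplicate_rate / (1 - config$duplicate_rate))
      if (n_dup > 0) {
        rows <- dplyr::bind_rows(rows, rows[sample.int(n0, n_dup, replace = TRUE), ])
      }
    }
    if (config$missing_elevation_rate >= 1) {
      rows$elevation <- NA_real_
    } else if (config$missing_elevation_rate > 0) {
      blank <- !rows$endpoint & runif(nrow(rows)) < config$missing_elevation_rate
      rows$elevation[blank] <- NA_real_
    }
    rows
  })
  rows <- res$value
  grid <- build_grid(mountain_id, config$min_elev, config$max_elev,
                     config$belt_width_m)
  truth_presence <- purrr::pmap(ranges, function(taxon, lo, hi) {
    i <- belt_index(lo, grid); j <- belt_index(hi, grid)
    grid$belt[i:j]
  })
  names(truth_presence) <- ranges$taxon
  occurrences <- tibble::tibble(taxon = rows$taxon, mountain = mountain_id,
                                elevation = rows$elevation,
                                source = ifelse(rows$endpoint, "herbarium", "plot"))
  list(occurrences = occurrences,
       truth = list(ranges = ranges, belt_presence = truth_presence,
                    grid = grid, seed = res$seed, config = config))
}

#' Simulate a per-belt area profile
#'
#' `hump`: unimodal areas with the maximum in the middle third of the
#' gradient (the typical mid-slope area bulge of large massifs);
#' `monotone`: strictly decreasing areas (a simple cone).
#'
#' @param grid A [build_grid()] result.
#' @param shape `"hump"` or `"monotone"`.
#' @param total_km2 Total mountain area to distribute.
#' @param seed Optional seed for the mild jitter on hump areas.
#' @return Tibble `(mountain_id, lo, area_km2)`, all areas positive.
#' @export
simulate_belt_areas <- function(grid, shape = c("hump", "monotone"),
                                total_km2 = 1000, seed = NULL) {
  shape <- match.arg(shape)
  n <- nrow(grid)
  res <- with_seed_reported(seed, {
    if (shape == "hump") {
      centre <- (n + 1) / 2
      w <- exp(-((seq_len(n) - centre) / (n / 4))^2)
      w <- w * runif(n, 0.95, 1.05)
      # keep the argmax inside the middle third despite jitter
      mid <- seq(ceiling(n / 3 + 1e-9), floor(2 * n / 3 + 1e-9))
      if (!which.max(w) %in% mid) w[round(centre)] <- max(w) * 1.1
    } else {
      w <- 0.85^(seq_len(n) - 1)
    }
    w
  })
  w <- res$value
  tibble::tibble(mountain_id = attr(grid, "mountain_id"), lo = grid$lo,
                 area_km2 = total_km2 * w / sum(w))
}

#' Assign native / non-native status to simulated species
#'
#' A uniformly chosen fraction `nonnative_fraction` of species is labelled
#' non-native and given fresh, relatively narrow elevational ranges whose
#' placement `nonnative_coupling` controls: with probability equal to the
#' coupling a non-native midpoint is sampled from the native richness
#' density (a uniform point inside a uniformly chosen native range), so
#' belt-level non-native richness tracks native richness — the pattern real
#' alien floras show; otherwise the midpoint is uniform on the span, which
#' decouples the two profiles.
#'
#' @param tree A `phylo` (supplies the species list).
#' @param ranges Tibble from [simulate_ranges()].
#' @param config A [scenario_config()].
#' @return List: `status` (tibble `taxon`, `native_status`) and `ranges`
#'   (the input ranges with non-native rows replaced).
#' @export
assign_nonnatives <- function(tree, ranges, config) {
  n <- ape::Ntip(tree)
  n_nn <- round(config$nonnative_fraction * n)
  span <- config$max_elev - config$min_elev
  res <- with_seed_reported(config$seed, {
    status <- rep("native", n)
    out_ranges <- ranges
    if (n_nn > 0) {
      pick <- sample.int(n, n_nn)
      status[pick] <- "non_native"
      native_idx <- setdiff(seq_len(n), pick)
      for (i in pick) {
        mid <- if (runif(1) < config$nonnative_coupling) {
          j <- native_idx[sample.int(length(native_idx), 1)]
          runif(1, ranges$lo[j], ranges$hi[j])
        } else {
          runif(1, config$min_elev, config$max_elev)
        }
        w <- min(rlnorm(1, log(0.08 * span), 0.5), 0.3 * span)
        out_ranges$lo[i] <- max(config$min_elev, mid - w / 2)
        out_ranges$hi[i] <- min(config$max_elev, mid + w / 2)
      }
    }
    list(status = status, ranges = out_ranges)
  })
  list(status = tibble::tibble(taxon = ranges$taxon,
                               native_status = res$value$status),
       ranges = res$value$ranges)
}

#' Simulate one complete synthetic mountain
#'
#' Chains [simulate_tree()], [simulate_ranges()], [simulate_occurrences()],
#' [simulate_belt_areas()] and [assign_nonnatives()] under one seed,
#' optionally writing the exact file formats the ingest/belt/phylo stages
#' consume (occurrence CSV, Newick, area CSV, alien list, truth JSON).
#'
#' @param config A [scenario_config()] (its `seed` drives everything).
#' @param mountain_id Mountain label.
#' @param area_shape Passed to [simulate_belt_areas()].
#' @param dir Optional output directory; when given, files are written.
#' @return List: `tree`, `ranges`, `occurrences`, `truth`, `areas`,
#'   `status`, `grid`, `config`, and (when written) `paths`.
#' @export
simulate_mountain <- function(config, mountain_id = "synthetic",
                              area_shape = "hump", dir = NULL) {
  seed <- with_seed_reported(config$seed, TRUE)$seed
  config$seed <- seed
  tree <- simulate_tree(config$n_species, seed = derive_seed(seed, 1))
  cfg_r <- config; cfg_r$seed <- derive_seed(seed, 2)
  ranges <- simulate_ranges(tree, cfg_r)
  cfg_n <- config; cfg_n$seed <- derive_seed(seed, 5)
  nn <- assign_nonnatives(tree, ranges, cfg_n)
  ranges <- nn$ranges
  status <- nn$status
  cfg_o <- config; cfg_o$seed <- derive_seed(seed, 3)
  occ <- simulate_occurrences(ranges, cfg_o, mountain_id = mountain_id)
  grid <- occ$truth$grid
  areas <- simulate_belt_areas(grid, shape = area_shape,
                               seed = derive_seed(seed, 4))
  out <- list(tree = tree, ranges = ranges, occurrences = occ$occurrences,
              truth = occ$truth, areas = areas, status = status, grid = grid,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      occurrences = file.path(dir, "occurrences.csv"),
      tree = file.path(dir, "tree.nwk"),
      areas = file.path(dir, "belt_areas.csv"),
      aliens = file.path(dir, "alien_list.txt"),
      truth = file.path(dir, "truth.json"))
    readr::write_csv(out$occurrences, paths$occurrences)
    ape::write.tree(tree, paths$tree)
    readr::write_csv(areas, paths$areas)
    writeLines(status$taxon[status$native_status == "non_native"], paths$aliens)
    jsonlite::write_json(
      list(seed = seed, scenario = config$scenario,
           ranges = out$truth$ranges,
           belt_presence = out$truth$belt_presence),
      paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
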