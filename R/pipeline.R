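#' Run configuration for a single-mountain analysis
#'
#' Collects every tunable decision of the pipeline in one validated object;
#' all of them are echoed into the run manifest so any output can be traced
#' to the exact conventions that produced it.
#'
#' @param mountain_id Mountain label.
#' @param synthetic Optional [scenario_config()]; when given, inputs are
#'   simulated and the path arguments are ignored.
#' @param occurrences,tree,areas,synonyms,taxonomy,aliens Input file paths
#'   (occurrence CSV, Newick, belt-area CSV, synonym CSV, taxonomy CSV,
#'   alien list). `occurrences` and `tree` are required unless `synthetic`
#'   is given; the rest are optional.
#' @param min_elev,max_elev Declared span; defaults to the synthetic span or
#'   the observed record range.
#' @param belt_width_m Belt width (default 100 m).
#' @param occupancy_mode `"record"` or `"range_through"`.
#' @param jaccard_convention,cody_convention Beta-diversity conventions.
#' @param null_scheme,n_reps NRI null-model scheme and replicate count.
#' @param include_root Faith's PD root convention.
#' @param drop_unresolved,keep_out_of_span Cleaning switches.
#' @param seed Integer seed (required: pipeline runs must be reproducible).
#' @return A `run_config` list.
#' @export
run_config <- function(mountain_id, synthetic = NULL,
                       occurrences = NULL, tree = NULL, areas = NULL,
                       synonyms = NULL, taxonomy = NULL, aliens = NULL,
                       min_elev = NULL, max_elev = NULL,
                       belt_width_m = 100,
                       occupancy_mode = c("record", "range_through"),
                       jaccard_convention = "unique_counts",
                       cody_convention = "half",
                       null_scheme = c("pool_draw", "taxa_label_shuffle"),
                       n_reps = 1000,
                       include_root = TRUE,
                       drop_unresolved = FALSE,
                       keep_out_of_span = FALSE,
                       seed = NULL) {
  occupancy_mode <- match.arg(occupancy_mode)
  null_scheme <- match.arg(null_scheme)
  if (is.null(seed)) abort("pipeline runs require an explicit seed")
  if (is.null(synthetic)) {
    for (p in c(occurrences, tree, areas, synonyms, taxonomy, aliens)) {
      if (!is.null(p) && !file.exists(p)) abort(paste0("input file missing: ", p))
    }
    if (is.null(occurrences) || is.null(tree)) {
      abort("occurrences and tree paths are required (or supply synthetic=)")
    }
  }
  structure(list(mountain_id = mountain_id, synthetic = synthetic,
                 occurrences = occurrences, tree = tree, areas = areas,
                 synonyms = synonyms, taxonomy = taxonomy, aliens = aliens,
                 min_elev = min_elev, max_elev = max_elev,
                 belt_width_m = belt_width_m, occupancy_mode = occupancy_mode,
                 jaccard_convention = jaccard_convention,
                 cody_convention = cody_convention,
                 null_scheme = null_scheme, n_reps = as.integer(n_reps),
                 include_root = include_root,
                 drop_unresolved = drop_unresolved,
                 keep_out_of_span = keep_out_of_span,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full single-mountain analysis
#'
#' Orchestrates ingest/cleaning, belt construction, alpha-diversity (SR,
#' PD, PE), adjacent-belt beta-diversity, the NRI profile, the trend fits
#' (richness~area when areas are present, NRI~elevation, NRI~richness,
#' native vs non-native correlation when statuses are present) and the
#' taxonomic summary. Deterministic given config + seed. When `out_dir` is
#' given, every result is serialized as CSV/JSON together with a
#' `manifest.json` recording the config hash, seed, package version, and
#' every convention flag.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List: `profile`, `beta`, `nri`, `trends` (tidy tibble),
#'   `summary`, `cleaning_report`, `peak_m`, `matrix`, `tree`, `manifest`.
#' @export
run_mountain <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  sim <- NULL
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- sc$seed %||% config$seed
    sc$belt_width_m <- config$belt_width_m
    sim <- stage("simulate", simulate_mountain(sc, mountain_id = config$mountain_id))
    occ_raw <- dplyr::rename(sim$occurrences, taxon_name = "taxon",
                             mountain_id = "mountain", elevation_m = "elevation")
    tree <- sim$tree
    areas <- sim$areas
    aliens <- sim$status$taxon[sim$status$native_status == "non_native"]
    taxonomy <- synonyms <- NULL
    lo0 <- sc$min_elev; hi0 <- sc$max_elev
  } else {
    occ_raw <- stage("ingest", read_occurrences(config$occurrences))
    tree <- stage("load_tree", load_tree(config$tree))
    areas <- if (!is.null(config$areas)) {
      readr::read_csv(config$areas, show_col_types = FALSE, progress = FALSE)
    }
    aliens <- if (!is.null(config$aliens)) read_alien_list(config$aliens)
              else character(0)
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
    synonyms <- if (!is.null(config$synonyms)) read_synonyms(config$synonyms)
    lo0 <- config$min_elev %||% min(occ_raw$elevation_m, na.rm = TRUE)
    hi0 <- config$max_elev %||% max(occ_raw$elevation_m, na.rm = TRUE)
  }

  spans <- setNames(list(c(lo0, hi0)), config$mountain_id)
  cleaned <- stage("clean", clean_occurrences(
    occ_raw, synonyms = synonyms, taxonomy = taxonomy, spans = spans,
    drop_unresolved = config$drop_unresolved,
    keep_out_of_span = config$keep_out_of_span))
  records <- tag_native_status(cleaned$records, aliens)

  grid <- stage("belts", build_grid(config$mountain_id, lo0, hi0,
                                    config$belt_width_m))
  matrix <- stage("belts", assign_belts(records, grid,
                                        mode = config$occupancy_mode,
                                        keep_out_of_span = TRUE))
  if (!is.null(areas)) matrix <- stage("areas", attach_areas(matrix, areas))

  matched <- stage("match", match_tree_matrix(tree, matrix))
  profile <- stage("alpha", diversity_profile(matrix, tree,
                                              include_root = config$include_root))
  beta <- stage("beta", suppressWarnings(adjacent_belt_profile(
    matrix, config$jaccard_convention, config$cody_convention)))
  nri_cfg <- null_model_config(n_reps = config$n_reps,
                               scheme = config$null_scheme,
                               seed = config$seed)
  nrip <- stage("nri", suppressWarnings(nri_profile(matched$tree, matrix, nri_cfg)))

  trend_rows <- list()
  if (!is.null(matrix$belt_area_km2)) {
    occ_belts <- dplyr::filter(profile, .data$sr > 0)
    trend_rows$area <- tidy(stage("trends", richness_area_fit(occ_belts)))
  }
  tr_nri <- tryCatch(nri_trend(nrip), error = function(e) NULL)
  if (!is.null(tr_nri)) {
    row <- tidy(tr_nri); row$extra <- tr_nri$trend
    trend_rows$nri_elev <- row
  }
  tr_sr <- tryCatch(nri_richness_fit(nrip, profile), error = function(e) NULL)
  if (!is.null(tr_sr)) trend_rows$nri_sr <- tidy(tr_sr)
  nncor <- tryCatch(
    native_nonnative_correlation(matrix,
      dplyr::distinct(records, taxon = .data$taxon_name, .data$native_status)),
    error = function(e) NULL)
  trends <- dplyr::bind_rows(trend_rows)

  tax_for_summary <- taxonomy %||% tibble::tibble(
    accepted_name = character(0), genus = character(0), family = character(0))
  summary <- suppressWarnings(stage("summary",
    summarize_mountain(records, tax_for_summary, config$mountain_id)))

  manifest <- list(
    mountain_id = config$mountain_id,
    package_version = as.character(utils::packageVersion("elevdiv")),
    seed = config$seed,
    belt_width_m = config$belt_width_m,
    belt_anchor = lo0,
    span = c(lo0, hi0),
    occupancy_mode = config$occupancy_mode,
    jaccard_convention = config$jaccard_convention,
    cody_convention = config$cody_convention,
    null_scheme = config$null_scheme,
    n_reps = config$n_reps,
    null_sd = "sample (n-1)",
    pd_include_root = config$include_root,
    pe_range_unit = "occupied belts within mountain",
    duplicate_rule = "accepted_name + mountain + elevation rounded to 1 m",
    drop_unresolved = config$drop_unresolved,
    keep_out_of_span = config$keep_out_of_span,
    peak_tie_rule = "lowest belt",
    synthetic_scenario = if (!is.null(config$synthetic)) config$synthetic$scenario
  )

  out <- list(profile = profile, beta = beta, nri = nrip, trends = trends,
              native_nonnative = nncor, summary = summary,
              cleaning_report = cleaned$report,
              peak_m = peak_elevation(profile),
              matrix = matrix, tree = matched$tree, manifest = manifest,
              synthetic = sim)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(profile, file.path(out_dir, "diversity_profile.csv"))
    readr::write_csv(beta, file.path(out_dir, "beta_profile.csv"))
    readr::write_csv(nrip, file.path(out_dir, "nri_profile.csv"))
    if (nrow(trends)) readr::write_csv(trends, file.path(out_dir, "trend_fits.csv"))
    if (!is.null(nncor)) {
      readr::write_csv(nncor, file.path(out_dir, "native_nonnative.csv"))
    }
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    write_belt_matrix(matrix, file.path(out_dir, "belt_matrix.csv"))
    cleaning_report_json(cleaned$report, file.path(out_dir, "cleaning_report.json"))
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(manifest_safe(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    manifest$peak_m <- out$peak_m
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    out$manifest <- manifest
    out$out_dir <- out_dir
  }
  out
}

# run_config with non-serializable pieces flattened for hashing.
manifest_safe <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

#' Cross-mountain synthesis
#'
#' Combines completed single-mountain runs: the species/genus/family
#' summary table with min/max/mean statistics, the per-mountain richness
#' peaks, and the peak-determinant fits against mountain attributes.
#'
#' @param results List of [run_mountain()] results (>= 4 mountains).
#' @param attributes Tibble with `mountain_id`, `relative_elevation_m`,
#'   `longitude_deg`, `amt_c`, `ap_mm`.
#' @param family Family for the determinant fits (see
#'   [peak_determinants()]).
#' @param out_dir Optional output directory for the CSV surfaces.
#' @return List: `summaries`, `stats`, `peaks`, `determinants`.
#' @export
run_cross_mountain <- function(results, attributes,
                               family = c("quasipoisson", "gaussian"),
                               out_dir = NULL) {
  family <- match.arg(family)
  if (length(results) < 4L) abort("need at least 4 completed mountain runs")
  summaries <- purrr::map_dfr(results, "summary")
  stats <- cross_mountain_stats(summaries)
  peaks <- purrr::map_dfr(results, function(r) {
    tibble::tibble(mountain_id = r$summary$mountain_id, peak_m = r$peak_m)
  })
  determinants <- peak_determinants(peaks, attributes, family = family)
  out <- list(summaries = summaries, stats = stats, peaks = peaks,
              determinants = determinants)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summaries, file.path(out_dir, "mountain_summaries.csv"))
    readr::write_csv(stats, file.path(out_dir, "cross_mountain_stats.csv"))
    readr::write_csv(peaks, file.path(out_dir, "peaks.csv"))
    readr::write_csv(determinants, file.path(out_dir, "peak_determinants.csv"))
  }
  out
}
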