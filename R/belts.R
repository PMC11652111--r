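#' Build a grid of fixed-width elevational belts
#'
#' Partitions a mountain's elevation span into belts of `belt_width_m`
#' metres (100 m by default, the convention in elevational-gradient
#' studies). Belts are half-open `[lo, lo + width)` so an elevation at an
#' exact belt boundary belongs to the upper belt; the summit belt is closed
#' at the top and truncated at the mountain's maximum elevation. The grid is
#' anchored at `min_elev_m` (the mountain base), not at sea level.
#'
#' @param mountain_id Mountain identifier.
#' @param min_elev_m,max_elev_m Declared elevation span in metres
#'   (`max > min`).
#' @param belt_width_m Belt width in metres (> 0), default 100.
#' @return A `belt_grid`: a tibble with columns `belt`, `lo`, `hi`,
#'   `midpoint` and attributes `mountain_id`, `belt_width_m`, `min_elev_m`,
#'   `max_elev_m`. Number of belts is `ceiling((max - min) / width)`.
#' @export
build_grid <- function(mountain_id, min_elev_m, max_elev_m, belt_width_m = 100) {
  if (!is.finite(min_elev_m) || !is.finite(max_elev_m) || max_elev_m <= min_elev_m) {
    abort("max_elev_m must exceed min_elev_m")
  }
  if (!is.finite(belt_width_m) || belt_width_m <= 0) abort("belt_width_m must be > 0")
  n <- ceiling((max_elev_m - min_elev_m) / belt_width_m)
  lo <- min_elev_m + (seq_len(n) - 1) * belt_width_m
  hi <- pmin(lo + belt_width_m, max_elev_m)
  grid <- tibble::tibble(belt = seq_len(n), lo = lo, hi = hi,
                         midpoint = (lo + hi) / 2)
  structure(grid, class = c("belt_grid", class(grid)),
            mountain_id = mountain_id, belt_width_m = belt_width_m,
            min_elev_m = min_elev_m, max_elev_m = max_elev_m)
}

# Belt index of elevations under the half-open convention; the summit
# elevation maps into the top belt. Returns NA outside the span.
belt_index <- function(elev, grid) {
  lo0 <- attr(grid, "min_elev_m")
  hi0 <- attr(grid, "max_elev_m")
  w <- attr(grid, "belt_width_m")
  idx <- floor((elev - lo0) / w) + 1L
  idx[elev == hi0] <- nrow(grid)
  idx[elev < lo0 | elev > hi0] <- NA_integer_
  as.integer(idx)
}

#' Build the belt-by-taxon presence/absence matrix
#'
#' Under `mode = "record"` a species occupies exactly the belts that contain
#' at least one of its records (faithful to specimen evidence). Under
#' `mode = "range_through"` it occupies every belt intersecting the interval
#' from its lowest to its highest record (the range-through assumption
#' common in elevational-gradient studies).
#'
#' @param records Cleaned occurrence tibble (single mountain).
#' @param grid A [build_grid()] result for that mountain.
#' @param mode Occupancy rule, `"record"` (default) or `"range_through"`.
#' @param keep_out_of_span If `TRUE`, records outside the grid span are
#'   dropped with a warning instead of raising an error.
#' @return A `belt_matrix`: list with the `grid`, the character vector
#'   `taxa` (sorted), the binary `presence` matrix (belts x taxa), the
#'   occupancy `mode` and the `mountain_id`. Every taxon column has at least
#'   one presence.
#' @export
assign_belts <- function(records, grid, mode = c("record", "range_through"),
                         keep_out_of_span = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "belt_grid"))
  records <- tibble::as_tibble(records)
  idx <- belt_index(records$elevation_m, grid)
  if (anyNA(idx)) {
    if (!keep_out_of_span) {
      bad <- records$elevation_m[is.na(idx)]
      abort(paste0(length(bad), " record(s) outside grid span [",
                   attr(grid, "min_elev_m"), ", ", attr(grid, "max_elev_m"),
                   "], e.g. ", paste(head(bad, 3), collapse = ", ")))
    }
    warn(paste0(sum(is.na(idx)), " out-of-span record(s) ignored"))
    records <- records[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(records) == 0L) abort("no records within the grid span")

  taxa <- sort(unique(records$taxon_name))
  n_belt <- nrow(grid)
  presence <- matrix(0L, n_belt, length(taxa),
                     dimnames = list(NULL, taxa))
  if (mode == "record") {
    cells <- unique(cbind(idx, match(records$taxon_name, taxa)))
    presence[cells] <- 1L
  } else {
    rng <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(taxon = records$taxon_name, belt = idx),
                      .data$taxon),
      lo = min(.data$belt), hi = max(.data$belt), .groups = "drop")
    for (i in seq_len(nrow(rng))) {
      presence[rng$lo[i]:rng$hi[i], match(rng$taxon[i], taxa)] <- 1L
    }
  }
  structure(list(grid = grid, taxa = taxa, presence = presence, mode = mode,
                 mountain_id = attr(grid, "mountain_id")),
            class = "belt_matrix")
}

#' @export
print.belt_matrix <- function(x, ...) {
  cat("Belt matrix for mountain '", x$mountain_id, "': ",
      nrow(x$presence), " belts x ", length(x$taxa), " taxa (mode = ",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' Per-belt species richness of a belt matrix
#'
#' @param matrix A `belt_matrix`.
#' @return Tibble with `belt`, `lo`, `hi`, `midpoint`, `sr` (and `area_km2`
#'   when areas are attached).
#' @export
belt_richness <- function(matrix) {
  out <- tibble::as_tibble(matrix$grid)
  out$sr <- as.integer(rowSums(matrix$presence))
  if (!is.null(matrix$belt_area_km2)) out$area_km2 <- matrix$belt_area_km2
  out$mountain_id <- matrix$mountain_id
  dplyr::relocate(out, "mountain_id")
}

#' Attach per-belt areas to a belt matrix
#'
#' Belt areas (km^2) normally come from GIS processing of a DEM; here they
#' are supplied as a table keyed by mountain and belt lower bound.
#'
#' @param matrix A `belt_matrix`.
#' @param area_table Tibble with columns `mountain_id`, `lo`, `area_km2`.
#' @return The matrix with `belt_area_km2` populated for every belt.
#' @export
attach_areas <- function(matrix, area_table) {
  stopifnot(inherits(matrix, "belt_matrix"))
  at <- dplyr::filter(tibble::as_tibble(area_table),
                      .data$mountain_id == matrix$mountain_id)
  pos <- match(matrix$grid$lo, at$lo)
  if (anyNA(pos)) {
    missing <- matrix$grid$lo[is.na(pos)]
    abort(paste0("no area for belt(s) with lower bound: ",
                 paste(missing, collapse = ", ")))
  }
  areas <- at$area_km2[pos]
  if (any(!is.finite(areas) | areas <= 0)) {
    abort("belt areas must be positive and finite")
  }
  matrix$belt_area_km2 <- areas
  matrix
}

#' Long-format view of a belt matrix
#'
#' @param x A `belt_matrix`.
#' @param ... Unused.
#' @return Tibble `(mountain_id, belt, lo, hi, midpoint, taxon)` with one
#'   row per presence.
#' @method as_tibble belt_matrix
#' @export
as_tibble.belt_matrix <- function(x, ...) {
  ij <- which(x$presence == 1L, arr.ind = TRUE)
  out <- tibble::tibble(
    mountain_id = x$mountain_id,
    belt = x$grid$belt[ij[, 1]],
    lo = x$grid$lo[ij[, 1]],
    hi = x$grid$hi[ij[, 1]],
    midpoint = x$grid$midpoint[ij[, 1]],
    taxon = x$taxa[ij[, 2]]
  )
  dplyr::arrange(out, .data$belt, .data$taxon)
}

#' Write a belt matrix as a wide CSV
#'
#' Rows are belts (with lo/hi/midpoint and area columns when present),
#' columns are taxa, cells 0/1.
#'
#' @param matrix A `belt_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_belt_matrix <- function(matrix, path) {
  wide <- tibble::as_tibble(matrix$grid)
  wide$mountain_id <- matrix$mountain_id
  if (!is.null(matrix$belt_area_km2)) wide$area_km2 <- matrix$belt_area_km2
  wide <- dplyr::bind_cols(wide, tibble::as_tibble(matrix$presence))
  readr::write_csv(wide, path)
  invisible(path)
}

# Taxon set of one belt.
belt_taxa <- function(matrix, belt) {
  matrix$taxa[matrix$presence[belt, ] == 1L]
}
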