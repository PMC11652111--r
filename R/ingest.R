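#' Read occurrence records from a delimited text file
#'
#' Reads specimen/plot occurrence records (one row per observation) from a
#' comma- or tab-delimited UTF-8 file with a header row. Elevations that do
#' not parse as numbers become `NA` rather than being dropped, so the
#' cleaning step can count them.
#'
#' @param path Path to the delimited file.
#' @param column_map Named list mapping the roles `taxon`, `mountain`,
#'   `elevation` (and optionally `source`) to column names in the file.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param spans Optional named list `mountain_id -> c(min, max)` of declared
#'   elevation spans in metres; when supplied an `out_of_span` flag column is
#'   added.
#'
#' @return A tibble with columns `taxon_name`, `mountain_id`, `elevation_m`,
#'   optionally `source` and `out_of_span`.
#' @export
read_occurrences <- function(path,
                             column_map = list(taxon = "taxon",
                                               mountain = "mountain",
                                               elevation = "elevation"),
                             sep = NULL,
                             spans = NULL) {
  if (!file.exists(path)) abort(paste0("occurrence file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (length(header) && grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    warn("occurrence file is empty")
  }
  required <- c("taxon", "mountain", "elevation")
  for (role in required) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(paste0("required column for '", role, "' (",
                   col %||% "<unmapped>", ") not found in ", path))
    }
  }
  out <- tibble::tibble(
    taxon_name  = as.character(raw[[column_map$taxon]]),
    mountain_id = as.character(raw[[column_map$mountain]]),
    elevation_m = suppressWarnings(as.numeric(raw[[column_map$elevation]]))
  )
  src_col <- column_map$source
  if (!is.null(src_col) && src_col %in% names(raw)) {
    out$source <- as.character(raw[[src_col]])
  }
  if (!is.null(spans)) out <- flag_out_of_span(out, spans)
  out
}

#' Flag records whose elevation falls outside the mountain's declared span
#'
#' @param records Occurrence tibble with `mountain_id` and `elevation_m`.
#' @param spans Named list `mountain_id -> c(min, max)` in metres.
#' @return `records` with a logical `out_of_span` column (`NA` elevation or
#'   unknown mountain gives `FALSE`; missingness is handled separately).
#' @export
flag_out_of_span <- function(records, spans) {
  flag <- purrr::map2_lgl(records$mountain_id, records$elevation_m, function(m, e) {
    sp <- spans[[m]]
    if (is.null(sp) || is.na(e)) return(FALSE)
    e < sp[[1]] || e > sp[[2]]
  })
  dplyr::mutate(records, out_of_span = flag)
}

#' Read a two-column synonym table
#'
#' The table maps raw (possibly outdated or misspelled) names to accepted
#' names and stands in for online name-resolution services, keeping the
#' pipeline fully offline and reproducible. An accepted name may appear on
#' the left only if it maps to itself (no chains or cycles).
#'
#' @param path Delimited file with columns `raw_name`, `accepted_name`.
#' @return A tibble with columns `raw_name`, `accepted_name`.
#' @export
read_synonyms <- function(path) {
  syn <- readr::read_csv(path, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  if (!all(c("raw_name", "accepted_name") %in% names(syn))) {
    abort("synonym table needs columns raw_name, accepted_name")
  }
  validate_synonyms(syn)
}

validate_synonyms <- function(syn) {
  syn <- tibble::as_tibble(syn)[, c("raw_name", "accepted_name")]
  if (anyDuplicated(syn$raw_name)) {
    abort("synonym table maps some raw names more than once")
  }
  chained <- syn$accepted_name %in% syn$raw_name[syn$raw_name != syn$accepted_name]
  if (any(chained)) {
    abort(paste0("synonym table is not acyclic; accepted names that are also ",
                 "remapped raw names: ",
                 paste(unique(syn$accepted_name[chained]), collapse = ", ")))
  }
  syn
}

#' Read a taxonomy backbone (accepted name, genus, family, native status)
#'
#' @param path CSV with columns `accepted_name`, `genus`, `family` and
#'   optionally `native_status` (`native`/`non_native`).
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("accepted_name", "genus", "family")
  if (!all(need %in% names(tax))) {
    abort("taxonomy table needs columns accepted_name, genus, family")
  }
  if (anyDuplicated(tax$accepted_name)) abort("taxonomy accepted_name not unique")
  tax
}

#' Read a one-column list of non-native (alien) species
#'
#' @param path Text file, one accepted name per line.
#' @return Character vector of accepted names.
#' @export
read_alien_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Clean occurrence records
#'
#' Applies the standard herbarium-data hygiene steps, in order: (1) map raw
#' names through the synonym table (never touching mountain or elevation);
#' (2) drop records lacking an elevation; (3) drop records outside the
#' mountain's declared span (unless `keep_out_of_span`); (4) collapse exact
#' duplicates — same accepted name, mountain, and elevation rounded to 1 m —
#' to a single record; (5) report names absent from the taxonomy backbone,
#' dropping them only when `drop_unresolved = TRUE`. Cleaning is idempotent.
#'
#' @param records Occurrence tibble from [read_occurrences()].
#' @param synonyms Optional synonym tibble (`raw_name`, `accepted_name`).
#' @param taxonomy Optional taxonomy tibble with `accepted_name`.
#' @param spans Optional named list of declared spans (see
#'   [flag_out_of_span()]).
#' @param drop_unresolved Drop records whose name is absent from `taxonomy`?
#'   Default `FALSE`: unresolved names are kept verbatim and reported.
#' @param keep_out_of_span Retain records outside the declared span?
#' @return A list with elements `records` (cleaned tibble, `taxon_name` now
#'   an accepted name) and `report` (a `cleaning_report`: counts per removal
#'   class plus the unresolved-name list). The identity
#'   `n_in - (no_elevation + out_of_span + duplicates + unresolved_dropped)
#'   == n_out` always holds.
#' @export
clean_occurrences <- function(records, synonyms = NULL, taxonomy = NULL,
                              spans = NULL, drop_unresolved = FALSE,
                              keep_out_of_span = FALSE) {
  records <- tibble::as_tibble(records)
  n_in <- nrow(records)

  if (!is.null(synonyms)) {
    synonyms <- validate_synonyms(synonyms)
    idx <- match(records$taxon_name, synonyms$raw_name)
    hit <- !is.na(idx)
    records$taxon_name[hit] <- synonyms$accepted_name[idx[hit]]
  }

  missing_elev <- !is.finite(records$elevation_m)
  n_missing <- sum(missing_elev)
  records <- records[!missing_elev, , drop = FALSE]

  n_oos <- 0L
  if (!is.null(spans) && !keep_out_of_span) {
    records <- flag_out_of_span(records, spans)
    n_oos <- sum(records$out_of_span)
    records <- records[!records$out_of_span, , drop = FALSE]
    records$out_of_span <- NULL
  }

  key <- paste(records$taxon_name, records$mountain_id,
               round(records$elevation_m), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  unresolved <- character(0)
  n_unres_dropped <- 0L
  if (!is.null(taxonomy)) {
    unresolved <- sort(unique(records$taxon_name[
      !records$taxon_name %in% taxonomy$accepted_name]))
    if (drop_unresolved && length(unresolved)) {
      keep <- !records$taxon_name %in% unresolved
      n_unres_dropped <- sum(!keep)
      records <- records[keep, , drop = FALSE]
    }
  }

  if (nrow(records) == 0L) abort("no usable records after cleaning")

  report <- structure(
    list(n_in = n_in, n_out = nrow(records), no_elevation = n_missing,
         out_of_span = n_oos, duplicates = n_dup,
         unresolved_dropped = n_unres_dropped, unresolved_names = unresolved),
    class = "cleaning_report"
  )
  list(records = records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Occurrence cleaning report\n")
  cat("  records in:          ", x$n_in, "\n")
  cat("  no elevation removed:", x$no_elevation, "\n")
  cat("  out of span removed: ", x$out_of_span, "\n")
  cat("  duplicates collapsed:", x$duplicates, "\n")
  cat("  unresolved dropped:  ", x$unresolved_dropped,
      " (", length(x$unresolved_names), " unresolved names)\n", sep = "")
  cat("  records out:         ", x$n_out, "\n")
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `cleaning_report` from [clean_occurrences()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Label records as native or non-native
#'
#' The label is a pure function of the accepted name: a record is non-native
#' iff its name is on the supplied alien list (a local stand-in for a
#' national alien-flora catalogue).
#'
#' @param records Cleaned occurrence tibble.
#' @param alien_list Character vector of non-native accepted names (possibly
#'   empty).
#' @return `records` with a `native_status` column (`"native"` /
#'   `"non_native"`).
#' @export
tag_native_status <- function(records, alien_list = character(0)) {
  dplyr::mutate(records,
    native_status = ifelse(.data$taxon_name %in% alien_list,
                           "non_native", "native"))
}
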