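#' Per-mountain taxonomic summary
#'
#' Counts distinct accepted species, genera and families (and records) for
#' one mountain's cleaned occurrence records. Species with unknown genus or
#' family are still counted as species but excluded from the genus/family
#' tallies, with a warning.
#'
#' @param records Cleaned occurrence tibble for one mountain (accepted
#'   names).
#' @param taxonomy Tibble `(accepted_name, genus, family)`.
#' @param mountain_id Optional id; defaults to the records' single
#'   `mountain_id`.
#' @return One-row tibble: `mountain_id`, `n_species`, `n_genera`,
#'   `n_families`, `n_records`.
#' @export
summarize_mountain <- function(records, taxonomy, mountain_id = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(mountain_id)) {
    ids <- unique(records$mountain_id)
    if (length(ids) != 1L) abort("records span several mountains; pass mountain_id")
    mountain_id <- ids
  } else {
    records <- dplyr::filter(records, .data$mountain_id == !!mountain_id)
  }
  species <- unique(records$taxon_name)
  pos <- match(species, taxonomy$accepted_name)
  unknown <- species[is.na(pos)]
  if (length(unknown)) {
    warn(paste0(length(unknown), " species lack taxonomy; counted as species ",
                "but not toward genus/family totals"))
  }
  genera <- taxonomy$genus[pos[!is.na(pos)]]
  families <- taxonomy$family[pos[!is.na(pos)]]
  tibble::tibble(
    mountain_id = mountain_id,
    n_species = length(species),
    n_genera = dplyr::n_distinct(genera[!is.na(genera) & nzchar(genera)]),
    n_families = dplyr::n_distinct(families[!is.na(families) & nzchar(families)]),
    n_records = nrow(records))
}

#' Cross-mountain summary statistics
#'
#' Minimum, maximum and mean (rounded half-up to integer, the convention
#' that reproduces printed flora summaries exactly) of the per-mountain
#' species, genus and family counts.
#'
#' @param summaries Tibble of [summarize_mountain()] rows (>= 1).
#' @return Tibble with one row per rank (`species`, `genus`, `family`):
#'   `min`, `max`, `mean`.
#' @export
cross_mountain_stats <- function(summaries) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) == 0L) abort("no mountain summaries supplied")
  cols <- c(species = "n_species", genus = "n_genera", family = "n_families")
  purrr::map_dfr(names(cols), function(rank) {
    x <- summaries[[cols[[rank]]]]
    tibble::tibble(rank = rank, min = min(x), max = max(x),
                   mean = round_half_up(mean(x)))
  })
}
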