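#' Jaccard similarity between two assemblages
#'
#' With `a` and `b` the numbers of species unique to each belt and `c` the
#' number shared, the default convention is the standard Jaccard similarity
#' c / (a + b + c) = c / (|A| + |B| - c): 1 for identical assemblages, 0
#' for disjoint ones. `convention = "literal_totals"` instead reads `a` and
#' `b` as the two belts' total richness, giving c / (|A| + |B| + c); it is
#' provided only for comparison (it cannot reach 1).
#'
#' @param setA,setB Character vectors of species names (non-empty).
#' @param convention `"unique_counts"` (default) or `"literal_totals"`.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_similarity <- function(setA, setB,
                               convention = c("unique_counts", "literal_totals")) {
  convention <- match.arg(convention)
  st <- belt_pair_counts(setA, setB)
  if (st$nA + st$nB == 0L) abort("both assemblages empty")
  switch(convention,
    unique_counts  = st$c / (st$a + st$b + st$c),
    literal_totals = st$c / (st$nA + st$nB + st$c))
}

#' Cody turnover between two assemblages
#'
#' The default convention is the standard Cody index (gains + losses)/2 =
#' (|A| + |B| - 2c)/2, where c is the shared-species count: 0 for identical
#' assemblages and growing with turnover. `convention = "over_c"` divides by
#' c instead (a literal reading of an ambiguously typeset formula) and is
#' undefined when no species are shared.
#'
#' @inheritParams jaccard_similarity
#' @param convention `"half"` (default) or `"over_c"`.
#' @return Non-negative numeric.
#' @export
cody_index <- function(setA, setB, convention = c("half", "over_c")) {
  convention <- match.arg(convention)
  st <- belt_pair_counts(setA, setB)
  if (st$nA + st$nB == 0L) abort("both assemblages empty")
  turnover <- st$nA + st$nB - 2 * st$c
  if (convention == "half") return(turnover / 2)
  if (st$c == 0L) abort("cody_index over_c undefined when no species are shared")
  turnover / st$c
}

# Partition counts of two species sets: a unique to A, b unique to B,
# c shared.
belt_pair_counts <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  c_shared <- length(intersect(setA, setB))
  list(nA = length(setA), nB = length(setB),
       a = length(setA) - c_shared, b = length(setB) - c_shared,
       c = c_shared)
}

#' Beta-diversity profile over adjacent elevational belts
#'
#' Computes Jaccard similarity and Cody turnover for each consecutive pair
#' of non-empty belts, ascending the mountain. Empty belts are skipped with
#' a warning rather than treated as zero-similarity communities.
#'
#' @param matrix A `belt_matrix`.
#' @param jaccard_convention,cody_convention Conventions forwarded to
#'   [jaccard_similarity()] and [cody_index()].
#' @return Tibble with one row per adjacent non-empty belt pair:
#'   `mountain_id`, `belt_lo`, `belt_hi` (belt indices), `pair`
#'   ("lo1-lo2" on elevations), `a`, `b`, `c`, `beta_j`, `beta_c`, and the
#'   conventions used.
#' @export
adjacent_belt_profile <- function(matrix,
                                  jaccard_convention = "unique_counts",
                                  cody_convention = "half") {
  stopifnot(inherits(matrix, "belt_matrix"))
  occ <- which(rowSums(matrix$presence) > 0L)
  if (length(occ) < nrow(matrix$presence)) {
    warn(paste0(nrow(matrix$presence) - length(occ),
                " empty belt(s) skipped in beta-diversity profile"))
  }
  if (length(occ) < 2L) abort("need at least 2 non-empty belts")
  purrr::map_dfr(seq_len(length(occ) - 1L), function(k) {
    i <- occ[k]; j <- occ[k + 1L]
    A <- belt_taxa(matrix, i); B <- belt_taxa(matrix, j)
    st <- belt_pair_counts(A, B)
    tibble::tibble(
      mountain_id = matrix$mountain_id,
      belt_lo = i, belt_hi = j,
      pair = paste0(matrix$grid$lo[i], "-", matrix$grid$lo[j]),
      a = st$a, b = st$b, c = st$c,
      beta_j = jaccard_similarity(A, B, jaccard_convention),
      beta_c = cody_index(A, B, cody_convention),
      jaccard_convention = jaccard_convention,
      cody_convention = cody_convention)
  })
}
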