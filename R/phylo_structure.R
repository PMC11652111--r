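#' Mean pairwise phylogenetic distance of a taxon set
#'
#' Mean of patristic (path-length) distances over all unordered pairs of
#' taxa in the set.
#'
#' @param tree A `phylo` object.
#' @param taxon_set Character vector of at least two tip labels.
#' @return Numeric scalar.
#' @export
mpd <- function(tree, taxon_set) {
  taxon_set <- unique(taxon_set)
  if (length(taxon_set) < 2L) abort("mpd needs at least 2 taxa")
  unknown <- setdiff(taxon_set, tree$tip.label)
  if (length(unknown)) abort(paste0("taxa not in tree: ",
                                    paste(unknown, collapse = ", ")))
  D <- ape::cophenetic.phylo(tree)[taxon_set, taxon_set]
  mean(D[lower.tri(D)])
}

mpd_from_dist <- function(D, idx) {
  sub <- D[idx, idx]
  mean(sub[lower.tri(sub)])
}

#' Null-model configuration for the net relatedness index
#'
#' @param n_reps Number of randomized communities (default 1000, the
#'   standard choice).
#' @param scheme `"pool_draw"` (default): each null community is a uniform
#'   sample without replacement from the species pool; or
#'   `"taxa_label_shuffle"`: tip labels of the pool subtree are permuted and
#'   the community is read off at its original positions. For MPD the two
#'   induce the same null distribution; both are offered because published
#'   analyses differ in which they report.
#' @param seed Integer seed; `NULL` draws one and reports it.
#' @param pool Character vector of pool taxa; `NULL` means all tree tips
#'   (all species recorded on the mountain).
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_reps = 1000, scheme = c("pool_draw",
                                                        "taxa_label_shuffle"),
                              seed = NULL, pool = NULL) {
  scheme <- match.arg(scheme)
  if (n_reps < 2) abort("n_reps must be at least 2")
  structure(list(n_reps = as.integer(n_reps), scheme = scheme, seed = seed,
                 pool = pool),
            class = "null_model_config")
}

#' Net relatedness index of one community
#'
#' Standardized effect size of the mean pairwise phylogenetic distance:
#' NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null), where the null
#' distribution comes from `n_reps` randomized communities of the same size
#' drawn from the species pool. NRI > 0 indicates phylogenetic clustering
#' (co-occurring species more related than chance), NRI < 0 overdispersion.
#' The null sd is the sample (n-1) standard deviation. A degenerate null
#' (sd = 0, e.g. community = pool under label shuffling, or a star tree) is
#' flagged, never silently zeroed.
#'
#' @param tree A `phylo` containing pool and community.
#' @param community Character vector of at least two tip labels, a subset of
#'   the pool.
#' @param config A [null_model_config()].
#' @return An `nri_result` list: `mpd_obs`, `null_mean`, `null_sd`, `nri`,
#'   `rank_p` = (1 + #\{null <= obs\}) / (n_reps + 1), `n_taxa`,
#'   `degenerate`, plus the scheme, n_reps and seed used.
#' @export
nri <- function(tree, community, config = null_model_config()) {
  community <- unique(community)
  if (length(community) < 2L) abort("community needs at least 2 taxa")
  pool <- config$pool %||% tree$tip.label
  if (!all(community %in% pool)) abort("community must be a subset of the pool")
  if (!all(pool %in% tree$tip.label)) abort("pool taxa missing from tree")
  D <- ape::cophenetic.phylo(tree)
  res <- with_seed_reported(config$seed, {
    nri_engine(D, pool, community, config$n_reps, config$scheme)
  })
  out <- res$value
  out$scheme <- config$scheme
  out$n_reps <- config$n_reps
  out$seed <- res$seed
  structure(out, class = "nri_result")
}

# Core Monte-Carlo engine, shared by nri() and nri_profile(). `D` is the
# full cophenetic matrix with dimnames.
nri_engine <- function(D, pool, community, n_reps, scheme) {
  k <- length(community)
  obs <- mpd_from_dist(D, community)
  null_mpd <- vapply(seq_len(n_reps), function(r) {
    idx <- if (scheme == "pool_draw") {
      sample(pool, k)
    } else {
      # permute the pool's labels; the community's members land on random
      # tips of the pool subtree
      setNames(sample(pool), pool)[community]
    }
    mpd_from_dist(D, idx)
  }, numeric(1))
  mu <- mean(null_mpd)
  sdv <- sd(null_mpd)
  degenerate <- !is.finite(sdv) || sdv == 0
  if (degenerate) {
    warn("null MPD distribution has zero spread; NRI undefined for this community")
  }
  list(mpd_obs = obs, null_mean = mu, null_sd = sdv,
       nri = if (degenerate) NA_real_ else -(obs - mu) / sdv,
       rank_p = (1 + sum(null_mpd <= obs)) / (n_reps + 1),
       n_taxa = k, degenerate = degenerate)
}

#' @export
print.nri_result <- function(x, ...) {
  cat("NRI: ", format(x$nri, digits = 4),
      "  (MPD obs ", format(x$mpd_obs, digits = 4),
      ", null ", format(x$null_mean, digits = 4),
      " +/- ", format(x$null_sd, digits = 4),
      "; rank p = ", format(x$rank_p, digits = 3),
      "; ", x$scheme, ", ", x$n_reps, " reps, seed ", x$seed, ")\n", sep = "")
  if (x$degenerate) cat("  [degenerate null: sd = 0]\n")
  invisible(x)
}

#' NRI along the elevational gradient
#'
#' Computes one NRI per belt with at least two taxa, against the pool of all
#' species recorded on the mountain (all tips of the matched tree). Belts
#' with fewer than two taxa are reported as not evaluable rather than
#' dropped. Per-belt seeds are derived deterministically from the config
#' seed, so results do not depend on evaluation order.
#'
#' @param tree A `phylo` matched to the matrix (see [match_tree_matrix()]).
#' @param matrix A `belt_matrix`.
#' @param config A [null_model_config()].
#' @return Tibble: `mountain_id`, `belt`, `midpoint`, `n_taxa`, `mpd_obs`,
#'   `null_mean`, `null_sd`, `nri`, `rank_p`, `evaluable`, `scheme`,
#'   `n_reps`, `seed`.
#' @export
nri_profile <- function(tree, matrix, config = null_model_config()) {
  m <- match_tree_matrix(tree, matrix)
  tree <- m$tree; matrix <- m$matrix
  pool <- config$pool %||% tree$tip.label
  D <- ape::cophenetic.phylo(tree)
  base <- with_seed_reported(config$seed, TRUE)$seed
  rows <- purrr::map_dfr(seq_len(nrow(matrix$grid)), function(b) {
    taxa <- belt_taxa(matrix, b)
    row <- tibble::tibble(
      mountain_id = matrix$mountain_id, belt = matrix$grid$belt[b],
      midpoint = matrix$grid$midpoint[b], n_taxa = length(taxa),
      mpd_obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
      nri = NA_real_, rank_p = NA_real_, evaluable = FALSE)
    if (length(taxa) < 2L) return(row)
    r <- withr::with_seed(derive_seed(base, b), {
      nri_engine(D, pool, taxa, config$n_reps, config$scheme)
    })
    row$mpd_obs <- r$mpd_obs; row$null_mean <- r$null_mean
    row$null_sd <- r$null_sd; row$nri <- r$nri; row$rank_p <- r$rank_p
    row$evaluable <- !r$degenerate
    row
  })
  if (!any(rows$evaluable)) warn("no evaluable belts (need >= 2 taxa and a non-degenerate null)")
  rows$scheme <- config$scheme
  rows$n_reps <- config$n_reps
  rows$seed <- base
  rows
}
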