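#' Load a rooted phylogeny from a Newick file
#'
#' Accepts standard Newick (quoted labels, polytomies allowed). Every branch
#' must carry a length and tip labels must be unique; trees with fewer than
#' two tips are rejected. Branch lengths may be in any consistent unit
#' (time or substitutions); all downstream indices are linear in them.
#'
#' @param path Newick file path.
#' @param text Alternatively, a Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
load_tree <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) abort("could not parse Newick input")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (ape::Ntip(tree) < 2L) abort("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge))
           else which(is.na(tree$edge.length))
    abort(paste0("branch length missing on edge(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  tree
}

#' Restrict a tree and a belt matrix to their shared taxa
#'
#' @param tree A `phylo` object.
#' @param matrix A `belt_matrix`.
#' @return List with the pruned `tree`, the restricted `matrix`, and a
#'   `report` naming taxa dropped from each side. Errors if fewer than two
#'   taxa are shared.
#' @export
match_tree_matrix <- function(tree, matrix) {
  shared <- intersect(tree$tip.label, matrix$taxa)
  if (length(shared) < 2L) abort("fewer than 2 taxa shared between tree and matrix")
  dropped_tree <- setdiff(tree$tip.label, shared)
  dropped_matrix <- setdiff(matrix$taxa, shared)
  if (length(dropped_tree)) tree <- ape::keep.tip(tree, shared)
  if (length(dropped_matrix)) {
    keep <- matrix$taxa %in% shared
    matrix$presence <- matrix$presence[, keep, drop = FALSE]
    matrix$taxa <- matrix$taxa[keep]
  }
  list(tree = tree, matrix = matrix,
       report = list(dropped_from_tree = sort(dropped_tree),
                     dropped_from_matrix = sort(dropped_matrix)))
}

# Edge-by-tip descendant indicator (edges in tree$edge order). Postorder
# accumulation; works with polytomies.
edge_tip_indicator <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  edge <- tree$edge
  # node -> tips below it
  below <- matrix(FALSE, n_tip + n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (i in ape::postorder(tree)) {
    # postorder lists an edge after every edge in its child's subtree
    parent <- edge[i, 1]; child <- edge[i, 2]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  ind <- below[edge[, 2], , drop = FALSE]
  colnames(ind) <- tree$tip.label
  ind
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Sum of branch lengths of the minimal subtree spanning `taxon_set`; by
#' default the subtree is anchored at the root (the convention of the
#' standard community-phylogenetics toolchain), so a single taxon has PD
#' equal to its root-to-tip path. With `include_root = FALSE` only branches
#' below the set's most recent common ancestor count, and a singleton has
#' PD 0.
#'
#' @param tree A `phylo` object.
#' @param taxon_set Character vector of tip labels (non-empty).
#' @param include_root Anchor the spanning subtree at the root? Default
#'   `TRUE`.
#' @return Non-negative numeric scalar.
#' @export
faith_pd <- function(tree, taxon_set, include_root = TRUE) {
  taxon_set <- unique(taxon_set)
  if (length(taxon_set) == 0L) abort("taxon_set is empty")
  unknown <- setdiff(taxon_set, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("taxa not in tree: ", paste(unknown, collapse = ", ")))
  }
  ind <- edge_tip_indicator(tree)
  counts <- ind[, taxon_set, drop = FALSE] %*% rep(1, length(taxon_set))
  if (include_root) {
    sum(tree$edge.length[counts > 0])
  } else {
    sum(tree$edge.length[counts > 0 & counts < length(taxon_set)])
  }
}

#' Phylogenetic endemism per elevational belt
#'
#' Rosauer-style range-weighted PD along one mountain's gradient: each
#' branch's length is divided by its range size r(b), measured as the
#' number of belts in which at least one of its descendant tips occurs, and
#' PE of a belt is the sum of these down-weighted lengths over the branches
#' the belt touches. Narrowly distributed lineages therefore contribute
#' more. Summed over belts, PE returns exactly the root-anchored PD of the
#' full taxon set (each branch's weight is distributed across its r(b)
#' belts).
#'
#' @param tree A `phylo` pruned to the matrix taxa (see
#'   [match_tree_matrix()]).
#' @param matrix A `belt_matrix` over the same taxa.
#' @return Tibble `(mountain_id, belt, midpoint, pe)`; empty belts get PE 0
#'   with a warning.
#' @export
phylogenetic_endemism <- function(tree, matrix) {
  if (!setequal(tree$tip.label, matrix$taxa)) {
    abort("tree tips and matrix taxa differ; run match_tree_matrix() first")
  }
  ind <- edge_tip_indicator(tree)[, matrix$taxa, drop = FALSE]
  occ <- (ind %*% t(matrix$presence)) > 0          # edges x belts
  r <- rowSums(occ)                                 # belts occupying each branch
  w <- ifelse(r > 0, tree$edge.length / pmax(r, 1), 0)
  pe <- as.numeric(t(occ) %*% w)
  if (any(rowSums(matrix$presence) == 0L)) {
    warn("empty belt(s): PE reported as 0")
  }
  tibble::tibble(mountain_id = matrix$mountain_id, belt = matrix$grid$belt,
                 midpoint = matrix$grid$midpoint, pe = pe)
}

#' Per-belt alpha-diversity profile (SR, Faith's PD, PE)
#'
#' Computes the three alpha-diversity indices for every belt of a mountain:
#' species richness, root-anchored Faith's PD, and phylogenetic endemism.
#' Tree and matrix are matched internally; empty belts get SR = PD = PE = 0.
#'
#' @param matrix A `belt_matrix`.
#' @param tree A `phylo` covering (at least) the matrix taxa.
#' @param include_root Root convention passed to [faith_pd()].
#' @return A `diversity_profile` tibble: `mountain_id`, `belt`, `lo`, `hi`,
#'   `midpoint`, `sr`, `pd`, `pe`, plus `area_km2` when areas are attached
#'   and an `occupancy_mode` attribute.
#' @export
diversity_profile <- function(matrix, tree, include_root = TRUE) {
  m <- match_tree_matrix(tree, matrix)
  tree <- m$tree; matrix2 <- m$matrix
  ind <- edge_tip_indicator(tree)[, matrix2$taxa, drop = FALSE]
  counts <- ind %*% t(matrix2$presence)             # edges x belts
  sizes <- rowSums(matrix2$presence)
  pd <- vapply(seq_len(nrow(matrix2$grid)), function(b) {
    if (sizes[b] == 0L) return(0)
    if (include_root) sum(tree$edge.length[counts[, b] > 0])
    else sum(tree$edge.length[counts[, b] > 0 & counts[, b] < sizes[b]])
  }, numeric(1))
  pe <- suppressWarnings(phylogenetic_endemism(tree, matrix2))$pe
  out <- belt_richness(matrix)   # SR from the full matrix (all taxa)
  out$pd <- pd
  out$pe <- pe
  if ("area_km2" %in% names(out)) {
    out <- dplyr::relocate(out, "area_km2", .after = dplyr::last_col())
  }
  structure(out, class = c("diversity_profile", class(out)),
            occupancy_mode = matrix$mode)
}
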