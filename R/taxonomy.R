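#' @useDynLib orthoscout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The fixed rank ladder used for taxonomic distances and the minDist/maxDist
# pruning bounds. Index 0 = species ... 7 = superkingdom. Ranks below species
# (subspecies, strain, ...) and unranked nodes are off the ladder.
.RANK_LADDER <- c("species", "genus", "family", "order", "class",
                  "phylum", "kingdom", "superkingdom")

#' Index of a rank on the ladder
#'
#' @param rank character rank name.
#' @return 0-based integer index (species = 0, ..., superkingdom = 7).
#' @export
rank_index <- function(rank) {
  i <- match(rank, .RANK_LADDER)
  if (anyNA(i)) stop("rank not on the ladder: ", paste(rank[is.na(i)], collapse = ", "))
  i - 1L
}

#' Build a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns `id`, `parent`, `rank`, `name`. The
#'   root row has `parent` equal to its own id or `NA`.
#' @return a `taxonomy_tree` object.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("id", "parent", "rank", "name") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- suppressWarnings(as.integer(nodes$parent))
  if (anyDuplicated(nodes$id)) stop("duplicate taxon id")
  root <- nodes$id[is.na(nodes$parent) | nodes$parent == nodes$id]
  if (length(root) != 1L) stop("missing root (expected exactly one root row)")
  nodes$parent[nodes$id == root] <- NA_integer_
  orphan <- !is.na(nodes$parent) & !(nodes$parent %in% nodes$id)
  if (any(orphan)) {
    stop("orphan node: parent of ", paste(nodes$id[orphan], collapse = ","),
         " absent from table")
  }
  # cycle check: every node must reach the root
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle detected at node ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  tr <- structure(list(nodes = nodes, root = root), class = "taxonomy_tree")
  lv <- tree_leaves(tr)
  ranked <- nodes$rank[match(lv, nodes$id)]
  bad <- !(ranked %in% c("species", "subspecies", "strain"))
  if (any(bad)) {
    stop("leaf with rank above species: ",
         paste(lv[bad], collapse = ","))
  }
  tr
}

#' Read a taxonomy table
#'
#' Expects a UTF-8 tab-separated file with a header line and columns
#' `id`, `parent`, `rank`, `name` (NCBI-style: taxon id, parent taxon id,
#' rank, scientific name). The root row points to itself or has an empty
#' parent field.
#'
#' @param path file path.
#' @return a `taxonomy_tree`.
#' @export
load_taxonomy <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  names(tab) <- tolower(names(tab))
  if ("parent_id" %in% names(tab)) names(tab)[names(tab) == "parent_id"] <- "parent"
  taxonomy_tree(tab[, c("id", "parent", "rank", "name")])
}

#' Write a taxonomy table
#' @param tree a `taxonomy_tree`.
#' @param path output file.
#' @export
write_taxonomy <- function(tree, path) {
  out <- tree$nodes
  out$parent[is.na(out$parent)] <- out$id[is.na(out$parent)]
  names(out)[names(out) == "parent"] <- "parent_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes,",
      length(tree_leaves(x)), "leaves, root", x$root, "\n")
  invisible(x)
}

#' Leaf taxa of a taxonomy tree
#' @param tree a `taxonomy_tree`.
#' @return integer vector of leaf taxon ids (sorted).
#' @export
tree_leaves <- function(tree) {
  ids <- tree$nodes$id
  sort(ids[!(ids %in% tree$nodes$parent)])
}

# Path from a node to the root, inclusive.
tax_ancestry <- function(tree, id) {
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$id)
  if (!(id %in% tree$nodes$id)) stop("taxon not in tree: ", id)
  path <- integer(0)
  cur <- id
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- parent_of[[as.character(cur)]]
  }
  path
}

# Lowest common ancestor of two (or more) taxa.
tax_lca <- function(tree, ids) {
  paths <- lapply(ids, function(i) tax_ancestry(tree, i))
  common <- Reduce(intersect, paths)
  if (length(common) == 0L) stop("taxa share no ancestor")
  common[1L]  # intersect preserves order of the first path (leaf -> root)
}

#' Taxonomic distance between two leaves
#'
#' The distance is the rank-ladder index of the lowest *ranked* common
#' ancestor of `a` and `b` (species = 0, genus = 1, ..., superkingdom = 7).
#' Unranked common ancestors are skipped upward to the nearest ranked one;
#' if none exists (e.g. the shared node is an unranked root above the
#' superkingdoms) the distance is the top of the ladder, 7.
#'
#' @param tree a `taxonomy_tree`.
#' @param a,b leaf taxon ids.
#' @return non-negative integer distance.
#' @export
taxonomic_distance <- function(tree, a, b) {
  if (a == b) {
    if (!(a %in% tree$nodes$id)) stop("taxon not in tree: ", a)
    return(0L)
  }
  pa <- tax_ancestry(tree, a)
  pb <- tax_ancestry(tree, b)
  common <- pa[pa %in% pb]
  ranks <- tree$nodes$rank[match(common, tree$nodes$id)]
  idx <- match(ranks, .RANK_LADDER)  # NA for unranked / off-ladder
  ranked <- which(!is.na(idx))
  if (length(ranked) == 0L) return(7L)
  as.integer(idx[ranked[1L]] - 1L)
}

# Distances from one leaf to a set of leaves (vectorized helper).
taxonomic_distances <- function(tree, p0, ids) {
  vapply(ids, function(b) taxonomic_distance(tree, p0, b), integer(1))
}

#' Traversal order of leaves by increasing taxonomic distance
#'
#' Leaves are visited in order of increasing taxonomic distance to `p0`;
#' equidistant leaves are visited in a random order drawn from the seeded
#' generator, so repeated calls with the same seed give the same order.
#' `p0` itself is excluded.
#'
#' @param tree a `taxonomy_tree`.
#' @param p0 reference leaf taxon id.
#' @param rng_seed integer seed for the within-class shuffle.
#' @param leaves optional restriction to a subset of leaf ids.
#' @return integer vector of taxon ids.
#' @export
traversal_order <- function(tree, p0, rng_seed, leaves = NULL) {
  lv <- tree_leaves(tree)
  if (!(p0 %in% tree$nodes$id)) stop("p0 not in tree: ", p0)
  if (!is.null(leaves)) lv <- lv[lv %in% leaves]
  lv <- lv[lv != p0]
  if (length(lv) == 0L) return(integer(0))
  d <- taxonomic_distances(tree, p0, lv)
  with_seed(rng_seed, {
    ord <- unlist(lapply(sort(unique(d)), function(k) {
      cls <- lv[d == k]
      if (length(cls) > 1L) sample(cls) else cls
    }), use.names = FALSE)
    ord
  })
}

# Evaluate expr with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Keep only the given leaves (and their ancestors) in the tree.
restrict_to_leaves <- function(tree, keep) {
  keep_nodes <- unique(unlist(lapply(keep, function(i) tax_ancestry(tree, i))))
  nodes <- tree$nodes[tree$nodes$id %in% keep_nodes, , drop = FALSE]
  structure(list(nodes = nodes, root = tree$root), class = "taxonomy_tree")
}

#' Prune leaves outside the minDist/maxDist distance bounds
#'
#' Removes every leaf whose divergence from `p0` lies below the `min_dist`
#' rank or above the `max_dist` rank; internal nodes left without leaves
#' are dropped. A leaf whose lowest ranked common ancestor with `p0` *is*
#' the `min_dist` rank diverged within that rank and is therefore excluded
#' too: at the default genus bound, a second species of p0's genus is
#' pruned, and with `min_dist` above "species" so is `p0` itself (it leaves
#' the candidate pool by design). `min_dist = "species"` excludes nothing.
#'
#' @param tree a `taxonomy_tree`.
#' @param p0 reference leaf.
#' @param min_dist,max_dist rank names bounding the allowed distance.
#' @return pruned `taxonomy_tree`.
#' @export
prune_rank_bounds <- function(tree, p0, min_dist = "genus",
                              max_dist = "superkingdom") {
  lo <- .min_dist_cutoff(min_dist)
  hi <- rank_index(max_dist)
  if (rank_index(min_dist) > hi) stop("min_dist above max_dist on the rank ladder")
  lv <- tree_leaves(tree)
  d <- taxonomic_distances(tree, p0, lv)
  keep <- lv[d >= lo & d <= hi]
  restrict_to_leaves(tree, keep)
}

# Leaves with distance < cutoff are "closer than min_dist": divergence at
# the min_dist rank itself counts as within it (except at the ladder floor).
.min_dist_cutoff <- function(min_dist) {
  t <- rank_index(min_dist)
  if (t > 0L) t + 1L else 0L
}

#' Prune a selected primer taxon and its close relatives
#'
#' After an iteration selects primer taxon `pi`, remove `pi` and every leaf
#' whose divergence from either `p0` or `pi` lies within the `min_dist`
#' rank (see [prune_rank_bounds()] for the bound semantics; at the default
#' genus bound, congeners of `pi` are removed with it). Repeated
#' application guarantees that all primer taxa are pairwise at least
#' `min_dist` apart.
#'
#' @param tree a `taxonomy_tree` (the active search tree).
#' @param full_tree the unpruned tree used for distance queries (defaults to
#'   `tree`; pass the original tree when `p0` has already been pruned).
#' @param p0,pi leaf taxon ids.
#' @param min_dist rank name.
#' @return pruned `taxonomy_tree`.
#' @export
prune_after_iteration <- function(tree, p0, pi, min_dist = "genus",
                                  full_tree = tree) {
  lo <- .min_dist_cutoff(min_dist)
  lv <- tree_leaves(tree)
  d0 <- taxonomic_distances(full_tree, p0, lv)
  di <- taxonomic_distances(full_tree, pi, lv)
  keep <- lv[lv != pi & d0 >= lo & di >= lo]
  restrict_to_leaves(tree, keep)
}

#' Is `anc` on the path from `id` to the root?
#' @param tree a `taxonomy_tree`.
#' @param anc candidate ancestor taxon id.
#' @param id taxon id.
#' @return logical.
#' @export
is_ancestor_or_self <- function(tree, anc, id) {
  anc %in% tax_ancestry(tree, id)
}
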