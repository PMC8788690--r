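#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted NJ tree with `ape`: `variant = "bionj"` (the default,
#' matching the variance-weighted branch estimation of BIONJ) or
#' `variant = "classic"` (Saitou-Nei with the Studier-Keppler Q-criterion).
#' Both variants recover the generating tree exactly when the input matrix
#' is additive.  Negative branch-length estimates, which NJ can produce on
#' noisy data, are clamped to zero with the deficit transferred to the
#' adjacent branch so tip-to-tip path lengths through the pair are
#' preserved; the number of clamped branches is recorded in the
#' `"n_clamped"` attribute.
#'
#' @param dm Labeled symmetric distance matrix (e.g. from
#'   [pairwise_distances()]) with at least two labels.
#' @param variant `"bionj"` or `"classic"`.
#' @return An unrooted `phylo` tree whose tips are the matrix labels.
#' @export
nj_tree <- function(dm, variant = c("bionj", "classic")) {
  variant <- match.arg(variant)
  dm <- as.matrix(dm)
  if (nrow(dm) < 2L) abort("neighbor joining needs at least 2 taxa")
  if (is.null(rownames(dm))) abort("distance matrix must be labeled")
  if (max(abs(dm - t(dm))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(!is.finite(dm))) abort("distance matrix must be finite")
  tree <- if (nrow(dm) == 2L) {
    # single split: halve the distance onto each pendant edge
    structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2L, byrow = TRUE),
      edge.length = rep(dm[1L, 2L] / 2, 2L),
      tip.label = rownames(dm), Nnode = 1L
    ), class = "phylo", order = "cladewise")
  } else if (variant == "bionj") {
    ape::bionj(as.dist(dm))
  } else {
    ape::nj(as.dist(dm))
  }
  clamp_negative_edges(tree)
}

# Set negative edge lengths to zero and add the (negative) deficit to the
# parent edge, so paths crossing both edges keep their length.
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    up <- which(tree$edge[, 2L] == parent)
    if (length(up) == 1L) {
      tree$edge.length[up] <- tree$edge.length[up] + deficit
    }
  }
  attr(tree, "n_clamped") <- length(neg)
  tree
}

#' Patristic (tree path) distances between all tips
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A labeled symmetric matrix of tip-to-tip path lengths with a
#'   `"kind"` attribute of `"patristic"`.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  attr(d, "kind") <- "patristic"
  d
}

#' Read and write newick trees
#'
#' Wrappers over `ape` serialization with basic validation (duplicate tip
#' labels are rejected).  Topology, labels and branch lengths round-trip.
#'
#' @param tree A `phylo` object.
#' @param path File path; for `read_newick()` the file must contain one
#'   valid newick tree.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns the
#'   path invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) abort(sprintf("could not parse newick in '%s'", path))
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  tree
}
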