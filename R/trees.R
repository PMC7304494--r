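#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomerative clustering (UPGMA): repeatedly merge the
#' closest pair of clusters, with inter-cluster distance the size-weighted
#' arithmetic mean of member pairwise distances. Merge heights are the
#' linkage distances themselves and are non-decreasing (the ultrametric
#' property). Backed by [stats::hclust()] with `method = "average"`.
#'
#' @param d symmetric distance matrix with id dimnames.
#' @return an `hclust` object (subclass `upgma`).
#' @export
upgma <- function(d) {
  check_distance_matrix(d, tol = 1e-9)
  if (nrow(d) < 2) stop("need at least 2 leaves", call. = FALSE)
  h <- stats::hclust(stats::as.dist(d), method = "average")
  class(h) <- c("upgma", "hclust")
  h
}

#' Left-to-right leaf order of a dendrogram
#'
#' The order in which leaves appear in a plotted dendrogram; used to arrange
#' admixture bar plots and heatmap rows so that genetic similarity
#' translates into plot adjacency.
#'
#' @param h an `hclust`/`upgma` object.
#' @return character vector of leaf ids in dendrogram order.
#' @export
leaf_order <- function(h) {
  stopifnot(inherits(h, "hclust"))
  h$labels[h$order]
}

#' Cophenetic distances of a dendrogram
#'
#' @param h an `hclust`/`upgma` object.
#' @return symmetric matrix of cophenetic (merge-height) distances.
#' @export
cophenetic_matrix <- function(h) {
  as.matrix(stats::cophenetic(h))
}

#' Neighbor-joining tree of a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via [ape::nj()]); negative branch
#' lengths, which can arise from noisy non-additive input, are clamped to
#' zero. For an additive input matrix the leaf-to-leaf path lengths
#' reproduce the matrix exactly.
#'
#' @param d symmetric distance matrix with id dimnames, n >= 3.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  check_distance_matrix(d, tol = 1e-9)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 leaves", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Write a tree or dendrogram as newick
#'
#' Dendrograms are exported as rooted trees with branch lengths derived
#' from merge heights; labels containing newick metacharacters are quoted.
#'
#' @param tree a `phylo` or `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix of summed branch lengths between leaves.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Linkage table of a dendrogram
#'
#' @param h an `hclust` object.
#' @return tibble with one row per merge: `cluster_a`, `cluster_b`
#'   (negative = leaf index, positive = prior merge), `distance`, `size`.
#' @export
linkage_table <- function(h) {
  sizes <- integer(nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- sz(h$merge[i, 1]) + sz(h$merge[i, 2])
  }
  tibble::tibble(cluster_a = h$merge[, 1], cluster_b = h$merge[, 2],
                 distance = h$height, size = sizes)
}
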