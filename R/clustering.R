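#' Spatially constrained Ward hierarchy of site pairs
#'
#' Agglomerates the matched pairs under the Ward minimum-variance
#' criterion applied to their fluvial (river-km) distances: the
#' spatial-only limit of mixed feature/space constrained clustering,
#' where the compositional matrix receives zero weight and geography
#' alone defines the hierarchy. Ward is run via the Lance-Williams
#' recurrence on squared dissimilarities (`stats::hclust`,
#' method "ward.D", on d^2); only the cluster memberships at each cut
#' feed downstream, so merge heights are reported in squared river-km
#' units and tree topology is the contract.
#'
#' Fluvial distances between pairs built from approximate site matches
#' can violate the triangle inequality; the hierarchy is built regardless
#' and a warning is emitted.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal,
#'   labelled by pair id.
#' @return object of class `merge_tree`: a list with `hclust` (the fitted
#'   hierarchy), `labels`, and `n_leaves`.
#' @export
ward_dendrogram <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 leaves")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("negative distances")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("L", seq_len(nrow(D)))
  if (triangle_violated(D))
    warning("distance matrix violates the triangle inequality; ",
            "Ward hierarchy built regardless")
  hc <- stats::hclust(stats::as.dist(D^2), method = "ward.D")
  structure(list(hclust = hc, labels = rownames(D), n_leaves = nrow(D)),
            class = "merge_tree")
}

triangle_violated <- function(D, tol = 1e-8) {
  n <- nrow(D)
  if (n > 40) return(FALSE)  # spot check only for big inputs
  for (k in seq_len(n))
    if (any(D > outer(D[, k], D[k, ], `+`) + tol)) return(TRUE)
  FALSE
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> Ward hierarchy over %d leaves\n", x$n_leaves))
  invisible(x)
}

#' Cut a Ward hierarchy into K clusters
#'
#' Cluster ids are renumbered 1..K in order of each cluster's smallest
#' member label, so assignments are stable across K. Cuts of one tree
#' are nested: the K-cut refines the (K-1)-cut.
#'
#' @param tree a `merge_tree` from [ward_dendrogram()].
#' @param K number of clusters, between 1 and the number of leaves.
#' @return named integer vector mapping pair id to cluster id (1..K).
#' @export
cut_clusters <- function(tree, K) {
  if (K < 1 || K > tree$n_leaves) stop("K out of range 1..", tree$n_leaves)
  raw <- stats::cutree(tree$hclust, k = K)
  # renumber by smallest member label
  first <- tapply(names(raw), raw, function(s) sort(s)[1])
  ord <- rank(first[as.character(sort(unique(raw)))])
  out <- as.integer(ord[as.character(raw)])
  names(out) <- names(raw)
  out
}

#' Export a merge tree as Newick
#'
#' Branch lengths derive from the Ward merge heights (squared-distance
#' scale).
#'
#' @param tree a `merge_tree`.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export cluster memberships for a range of K as a long table
#'
#' @param tree a `merge_tree`.
#' @param path output TSV path (`pair_id`, `K`, `cluster_id`).
#' @param K_range integer vector of cuts (default all 1..n_leaves).
#' @export
write_cluster_cuts <- function(tree, path, K_range = seq_len(tree$n_leaves)) {
  rows <- do.call(rbind, lapply(K_range, function(K) {
    cl <- cut_clusters(tree, K)
    data.frame(pair_id = names(cl), K = K, cluster_id = unname(cl),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
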