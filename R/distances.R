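#' Rank-based pairwise distances from a partition tree
#'
#' Uses the rankings of the nested partitions to derive distances between
#' sequences. Let L be the number of internal nodes on the deepest
#' root-to-tip path. Two sequences first separated at an internal node at
#' depth r (root split r = 1) get distance `(L - r + 1) / L`, so
#' root-separated pairs are at the maximum distance 1 and pairs separated
#' deeper in the tree are closer. Sequences sharing a tip (indistinguishable
#' over the window) get distance 0. The matrix has one row/column per
#' sequence, not per tip.
#'
#' The normalization places distances in (0, 1]; any strictly monotone
#' transform of the ranks yields the same Mantel/dCor/HHG permutation tests,
#' so only the monotone structure is load-bearing.
#'
#' @param tree A `partition_tree` (or a simulated `genealogy`, whose leaves
#'   play the role of tips).
#' @return Symmetric numeric matrix with zero diagonal, dimnames the sequence
#'   names in original row order. A single-tip tree yields the all-zero
#'   matrix.
#' @export
rank_distance_matrix <- function(tree) UseMethod("rank_distance_matrix")

#' @export
rank_distance_matrix.partition_tree <- function(tree) {
  n <- length(tree$hap_names)
  d <- matrix(0, n, n, dimnames = list(tree$hap_names, tree$hap_names))
  internal <- which(!is.na(tree$rank))
  if (length(internal) == 0) return(d)
  L <- max(tree$depth[tree$tips])
  for (id in internal) {
    r <- tree$depth[id] + 1L
    left <- tree$members[[tree$child0[id]]]
    right <- tree$members[[tree$child1[id]]]
    d[left, right] <- (L - r + 1) / L
    d[right, left] <- (L - r + 1) / L
  }
  d
}

#' @export
rank_distance_matrix.genealogy <- function(tree) {
  g <- tree
  n <- length(g$labels)
  d <- matrix(0, n, n, dimnames = list(g$labels, g$labels))
  depth <- integer(length(g$parent))
  walk <- function(id, dep) {
    depth[id] <<- dep
    if (!is.na(g$child0[id])) {
      walk(g$child0[id], dep + 1L)
      walk(g$child1[id], dep + 1L)
    }
  }
  walk(g$root, 0L)
  L <- max(depth[seq_len(n)])  # leaves are nodes 1..n
  internal <- which(!is.na(g$child0))
  for (id in internal) {
    r <- depth[id] + 1L
    left <- g$members[[g$child0[id]]]
    right <- g$members[[g$child1[id]]]
    d[left, right] <- (L - r + 1) / L
    d[right, left] <- (L - r + 1) / L
  }
  d
}

#' Cut a partition tree into k clusters
#'
#' Replays the tree's splits in creation-rank order (the order in which the
#' recursive partitioning performed them, oldest SNV first — the analogue of
#' cutting a dendrogram at successively lower heights); after `k - 1` splits
#' the active clusters are the assignment. `k` equal to the number of tips
#' returns the tip partition.
#'
#' @param tree A `partition_tree`.
#' @param k Number of clusters, between 1 and `n_tips(tree)`.
#' @return An object of class `cluster_assignment`: named integer vector of
#'   cluster ids (1..k) over the sequence names, with attribute `k`.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "partition_tree"))
  nt <- length(tree$tips)
  if (k < 1 || k > nt)
    stop("k must be between 1 and the number of tips (", nt, ")", call. = FALSE)
  k <- as.integer(k)
  frontier <- 1L
  if (k > 1L) {
    for (r in seq_len(k - 1L)) {
      id <- which(!is.na(tree$rank) & tree$rank == r)
      frontier <- c(setdiff(frontier, id), tree$child0[id], tree$child1[id])
    }
  }
  ids <- integer(length(tree$hap_names))
  for (ci in seq_along(frontier)) {
    ids[tree$members[[frontier[ci]]]] <- ci
  }
  names(ids) <- tree$hap_names
  structure(ids, k = k, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", attr(x, "k"), "clusters over", length(x), "sequences\n")
  print(unclass(x))
  invisible(x)
}

#' Write a labelled square distance matrix as CSV
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(d, path, quote = FALSE)
  invisible(path)
}

#' Read a labelled square distance matrix from CSV
#' @param path Input path (header row and row-name column, as written by
#'   [write_distance_matrix()]).
#' @return Numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
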