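#' Recursively partition sequences on an ordered list of SNVs
#'
#' Builds the rooted binary partition tree underlying a window of SNVs.
#' Starting from a single cluster holding every sequence, the SNVs are
#' processed left to right; at each SNV every active multi-sequence cluster
#' that is polymorphic at that SNV splits into its allele-0 subcluster and its
#' allele-1 (derived-allele carrier) subcluster. A SNV monomorphic within a
#' cluster is skipped for that cluster, so every internal node has exactly two
#' children. The process stops when every cluster is a singleton or the SNV
#' list is exhausted; remaining multi-sequence clusters become tips whose
#' label joins the member names (in original row order) with `sep` — such
#' sequences are indistinguishable over the window.
#'
#' @param x A [hap_matrix()] object.
#' @param ordered_snvs Nonempty integer vector of column indices, in splitting
#'   order (typically from [order_neighborhood()]).
#' @param sep Separator used to join the names of indistinguishable sequences
#'   in a tip label (default `"-"`).
#' @return An object of class `partition_tree` (see Details).
#'
#' @details A `partition_tree` stores a flat node table: `parent` (0 for the
#'   root), `children` (integer pair per internal node, allele-0 child first),
#'   `snv_index`/`snv_name` and `rank` per internal node (rank 1 = first split
#'   performed), `members` (row indices under each node), and for tips a
#'   display `label`. No branch lengths are defined by the method; trees are
#'   topology-only.
#' @export
build_partition <- function(x, ordered_snvs, sep = "-") {
  stopifnot(inherits(x, "hap_matrix"))
  if (length(ordered_snvs) < 1) stop("ordered_snvs must be nonempty", call. = FALSE)
  if (any(ordered_snvs < 1 | ordered_snvs > ncol(x$mat)))
    stop("ordered_snvs contains out-of-range column indices", call. = FALSE)

  n <- nrow(x$mat)
  max_nodes <- 2L * n - 1L
  parent <- integer(max_nodes)
  child0 <- rep(NA_integer_, max_nodes)
  child1 <- rep(NA_integer_, max_nodes)
  snv_of <- rep(NA_integer_, max_nodes)
  rank_of <- rep(NA_integer_, max_nodes)
  depth <- integer(max_nodes)
  members <- vector("list", max_nodes)

  members[[1]] <- seq_len(n)
  n_nodes <- 1L
  open <- 1L
  next_rank <- 1L

  for (s in ordered_snvs) {
    if (all(lengths(members[open]) == 1L)) break
    col <- x$mat[, s]
    new_open <- integer(0)
    for (id in open) {
      rows <- members[[id]]
      if (length(rows) > 1L) {
        v <- col[rows]
        if (any(v == 0L) && any(v == 1L)) {
          c0 <- n_nodes + 1L
          c1 <- n_nodes + 2L
          n_nodes <- n_nodes + 2L
          parent[c(c0, c1)] <- id
          depth[c(c0, c1)] <- depth[id] + 1L
          members[[c0]] <- rows[v == 0L]
          members[[c1]] <- rows[v == 1L]
          child0[id] <- c0
          child1[id] <- c1
          snv_of[id] <- s
          rank_of[id] <- next_rank
          next_rank <- next_rank + 1L
          new_open <- c(new_open, c0, c1)
          next
        }
      }
      new_open <- c(new_open, id)
    }
    open <- new_open
  }

  keep <- seq_len(n_nodes)
  tips <- open
  labels <- rep(NA_character_, n_nodes)
  labels[tips] <- vapply(tips, function(id) {
    paste(x$hap_names[members[[id]]], collapse = sep)
  }, character(1))

  structure(
    list(
      parent = parent[keep],
      child0 = child0[keep], child1 = child1[keep],
      snv_index = snv_of[keep],
      snv_name = ifelse(is.na(snv_of[keep]), NA_character_, x$snv_names[snv_of[keep]]),
      rank = rank_of[keep],
      depth = depth[keep],
      members = members[keep],
      tips = tips,
      label = labels,
      hap_names = x$hap_names,
      sep = sep
    ),
    class = "partition_tree"
  )
}

#' @export
print.partition_tree <- function(x, ...) {
  cat("partition_tree:", length(x$hap_names), "sequences,",
      length(x$tips), "tips,", sum(!is.na(x$rank)), "splits\n")
  meta <- attr(x, "window")
  if (!is.null(meta)) {
    cat("focal SNV:", meta$focal_name, "  window:",
        format(meta$lower_pos, big.mark = ","), "-",
        format(meta$upper_pos, big.mark = ","), "bp\n")
  }
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Number of tips of a partition tree
#' @param tree A `partition_tree`.
#' @return Integer tip count.
#' @export
n_tips <- function(tree) {
  stopifnot(inherits(tree, "partition_tree"))
  length(tree$tips)
}

#' Reconstruct the local perfect phylogeny at a focal SNV
#'
#' Composition of [select_neighborhood()] (four-gamete window growth around
#' the focal SNV, padded to the minimum window size by physical proximity),
#' [order_neighborhood()] (compatible SNVs most-ancient-first by minor allele
#' frequency, then padding SNVs by proximity), and [build_partition()]
#' (recursive partitioning). The returned tree carries a `"window"` attribute
#' recording the focal SNV and the base-pair limits of the neighborhood.
#'
#' @param x A [hap_matrix()] object.
#' @param focal Column index of the focal SNV.
#' @param min_window Minimum neighborhood size; defaults to the larger of one
#'   and 2% of the number of SNVs ([default_min_window()]).
#' @param sep Tip-label separator for indistinguishable sequences.
#' @return A `partition_tree` with window metadata.
#' @examples
#' sim <- simulate_region(n_seq = 10, n_snv = 20, seed = 1)
#' tr <- reconstruct_partition(sim$hapmat, focal = 1)
#' tr
#' @export
reconstruct_partition <- function(x, focal,
                                  min_window = default_min_window(ncol(x$mat)),
                                  sep = "-") {
  nbhd <- select_neighborhood(x, focal, min_window)
  ord <- order_neighborhood(x, nbhd)
  tree <- build_partition(x, ord, sep = sep)
  attr(tree, "window") <- list(
    focal_index = nbhd$focal,
    focal_name = x$snv_names[nbhd$focal],
    lower_index = nbhd$lower, upper_index = nbhd$upper,
    lower_pos = nbhd$lower_pos, upper_pos = nbhd$upper_pos,
    compatible = nbhd$compatible, incompatible = nbhd$incompatible,
    ordered_snvs = ord
  )
  tree
}

#' Reconstruct local perfect phylogenies across a genomic region
#'
#' Runs [reconstruct_partition()] at each focal SNV in turn. When subregion
#' bounds are given, focal SNVs are exactly those whose position lies in
#' `[from, to]` (inclusive); neighborhoods may still extend beyond the bounds,
#' which restrict focal SNVs only.
#'
#' @param x A [hap_matrix()] object.
#' @param min_window,sep Passed to [reconstruct_partition()].
#' @param from,to Optional subregion bounds in base pairs (inclusive).
#' @return An object of class `region_scan`: list with `trees` (one
#'   `partition_tree` per focal SNV), `focal_indices`, `pos` (their base-pair
#'   positions), and `hap_names`.
#' @export
reconstruct_region <- function(x, min_window = default_min_window(ncol(x$mat)),
                               sep = "-", from = NULL, to = NULL) {
  stopifnot(inherits(x, "hap_matrix"))
  if (!is.null(from) && !is.null(to) && from > to)
    stop("subregion lower bound exceeds upper bound", call. = FALSE)
  idx <- seq_len(ncol(x$mat))
  if (!is.null(from)) idx <- idx[x$pos[idx] >= from]
  if (!is.null(to)) idx <- idx[x$pos[idx] <= to]
  if (length(idx) == 0)
    stop("no focal SNVs fall inside the requested subregion", call. = FALSE)
  trees <- lapply(idx, function(i) {
    reconstruct_partition(x, i, min_window = min_window, sep = sep)
  })
  structure(
    list(trees = trees, focal_indices = idx, pos = x$pos[idx],
         snv_names = x$snv_names[idx], hap_names = x$hap_names),
    class = "region_scan"
  )
}

#' @export
print.region_scan <- function(x, ...) {
  cat("region_scan:", length(x$trees), "reconstructed partitions over",
      format(x$pos[1], big.mark = ","), "-",
      format(x$pos[length(x$pos)], big.mark = ","), "bp\n")
  invisible(x)
}

#' @export
length.region_scan <- function(x) length(x$trees)

#' Newick serialization of a partition tree
#'
#' Multi-sequence tips appear as single leaves carrying their joined label.
#' The method defines no branch lengths, so the output is topology-only. When
#' `annotate = TRUE`, internal nodes are labelled with their splitting SNV
#' name. A single-tip tree is written as `"(<label>);"`.
#'
#' @param tree A `partition_tree`.
#' @param annotate Write splitting-SNV names as internal node labels?
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, annotate = FALSE) {
  stopifnot(inherits(tree, "partition_tree"))
  rec <- function(id) {
    if (is.na(tree$child0[id])) return(tree$label[id])
    inner <- paste0("(", rec(tree$child0[id]), ",", rec(tree$child1[id]), ")")
    if (annotate) paste0(inner, tree$snv_name[id]) else inner
  }
  if (is.na(tree$child0[1])) {
    paste0("(", tree$label[1], ");")
  } else {
    paste0(rec(1L), ";")
  }
}

#' Convert a partition tree to an ape phylo object
#'
#' @param tree A `partition_tree`.
#' @return An [ape::read.tree()]-parsed `phylo` object with one leaf per tip
#'   (indistinguishable sequences remain joined in one leaf label).
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = to_newick(tree))
}

#' Plain-text window report for a reconstructed tree
#'
#' @param tree A `partition_tree` from [reconstruct_partition()].
#' @param x The `hap_matrix` the tree was reconstructed from (for SNV names).
#' @return Character vector of report lines: focal SNV, window limits in bp,
#'   and the compatible and incompatible SNV name lists.
#' @export
window_report <- function(tree, x) {
  meta <- attr(tree, "window")
  if (is.null(meta)) stop("tree carries no window metadata", call. = FALSE)
  c(
    paste0("focal_snv: ", meta$focal_name),
    paste0("window_bp: ", format(meta$lower_pos, scientific = FALSE, trim = TRUE),
           " - ", format(meta$upper_pos, scientific = FALSE, trim = TRUE)),
    paste0("compatible: ", paste(x$snv_names[meta$compatible], collapse = ",")),
    paste0("incompatible: ", paste(x$snv_names[meta$incompatible], collapse = ","))
  )
}
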