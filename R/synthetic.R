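# Seeded generators for haplotype data with known ancestral structure:
# random genealogies, infinite-sites mutations, recombination breakpoints
# separating independent genealogies, and binary phenotypes driven by causal
# variants in a subregion. Topology-only genealogies (no coalescent waiting
# times) are used because the reconstruction itself uses no branch lengths;
# uniform-over-branches mutation placement is a documented simplification of
# the infinite-sites coalescent.

#' Simulate a random genealogy topology
#'
#' Builds a rooted binary tree over `n_seq` labelled sequences by iterative
#' uniform random pairwise joins (a Yule-process topology). Every labelled
#' pair is equally likely to be the first join.
#'
#' @param n_seq Number of sequences (>= 2).
#' @param seed Optional RNG seed.
#' @param labels Sequence labels (default `h1`, `h2`, ...).
#' @return An object of class `genealogy`: flat node table with `parent`,
#'   `child0`/`child1`, `members` (leaf labels under each node), `root` id,
#'   and `labels`.
#' @export
simulate_genealogy <- function(n_seq, seed = NULL, labels = paste0("h", seq_len(n_seq))) {
  if (n_seq < 2) stop("need at least 2 sequences", call. = FALSE)
  stopifnot(length(labels) == n_seq)
  with_rng_seed(seed, {
    max_nodes <- 2L * n_seq - 1L
    parent <- integer(max_nodes)
    child0 <- rep(NA_integer_, max_nodes)
    child1 <- rep(NA_integer_, max_nodes)
    members <- vector("list", max_nodes)
    for (i in seq_len(n_seq)) members[[i]] <- labels[i]
    active <- seq_len(n_seq)
    nxt <- n_seq
    while (length(active) > 1) {
      pick <- sample(length(active), 2)
      a <- active[pick[1]]; b <- active[pick[2]]
      nxt <- nxt + 1L
      parent[c(a, b)] <- nxt
      child0[nxt] <- a; child1[nxt] <- b
      members[[nxt]] <- c(members[[a]], members[[b]])
      active <- c(active[-pick], nxt)
    }
    structure(
      list(parent = parent, child0 = child0, child1 = child1,
           members = members, root = nxt, labels = labels),
      class = "genealogy"
    )
  })
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy over", length(x$labels), "sequences\n")
  cat(genealogy_newick(x), "\n")
  invisible(x)
}

#' Newick string for a simulated genealogy (topology only)
#' @param g A `genealogy`.
#' @return Newick string.
#' @export
genealogy_newick <- function(g) {
  rec <- function(id) {
    if (is.na(g$child0[id])) return(g$members[[id]])
    paste0("(", rec(g$child0[id]), ",", rec(g$child1[id]), ")")
  }
  paste0(rec(g$root), ";")
}

#' Clade leaf-sets of a genealogy
#'
#' The leaf set below every non-root node (the carriers of a mutation on the
#' branch above that node). Under the infinite-sites model, every simulated
#' SNV's derived-allele carrier set is one of these clades.
#'
#' @param g A `genealogy`.
#' @param include_tips Include singleton (leaf) clades? Default `TRUE`.
#' @return List of character vectors of sequence labels.
#' @export
clade_sets <- function(g, include_tips = TRUE) {
  ids <- setdiff(which(g$parent != 0L), integer(0))
  if (!include_tips) ids <- ids[!is.na(g$child0[ids])]
  lapply(ids, function(id) g$members[[id]])
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each SNV is placed on one branch chosen uniformly among the branches of
#' the genealogy (every non-root node has one branch above it); the derived
#' allele (coded 1) is carried by exactly the leaves below that branch. With
#' a single genealogy and no recombination, every resulting column pair
#' passes the four-gamete test.
#'
#' @param g A `genealogy`.
#' @param n_snv Number of SNVs to drop (>= 1).
#' @param pos Strictly increasing base-pair positions, one per SNV.
#' @param seed Optional RNG seed.
#' @param snv_names SNV labels (default `snv1`, ...).
#' @return A [hap_matrix()] with attribute `"mutation_nodes"` recording the
#'   node id each SNV's mutation sits above.
#' @export
drop_mutations <- function(g, n_snv, pos, seed = NULL,
                           snv_names = paste0("snv", seq_len(n_snv))) {
  if (n_snv < 1) stop("n_snv must be >= 1", call. = FALSE)
  stopifnot(length(pos) == n_snv)
  with_rng_seed(seed, {
    branch_nodes <- which(g$parent != 0L)
    chosen <- branch_nodes[sample.int(length(branch_nodes), n_snv, replace = TRUE)]
    mat <- matrix(0L, nrow = length(g$labels), ncol = n_snv)
    rownames(mat) <- g$labels
    for (j in seq_len(n_snv)) {
      mat[g$members[[chosen[j]]], j] <- 1L
    }
    out <- hap_matrix(mat, snv_names = snv_names, hap_names = g$labels, pos = pos)
    attr(out, "mutation_nodes") <- chosen
    out
  })
}

#' Simulate a genomic region of haplotypes, optionally with recombination
#'
#' SNV positions are drawn uniformly over the region. Recombination
#' breakpoints cut the region into segments; each segment receives an
#' independent random genealogy and its own infinite-sites mutations, so SNV
#' pairs within a segment are always four-gamete compatible while pairs
#' straddling a breakpoint need not be. The draw is rejected and retried
#' (whole-region redraw of genealogies and mutations, up to `max_tries`)
#' until every adjacent segment pair shows at least one incompatible
#' cross-boundary SNV pair, so windowing has a boundary to detect.
#'
#' @param n_seq Number of sequences.
#' @param n_snv Number of SNVs across the region.
#' @param breakpoints Base-pair positions of recombination breakpoints
#'   (default none: a single shared genealogy).
#' @param region Length-2 base-pair range (default 1 bp - 2 Mbp, matching a
#'   population-scale fine-mapping region).
#' @param seed Optional RNG seed; the full object is reproducible from it.
#' @param max_tries Rejection cap for the cross-breakpoint incompatibility
#'   guarantee.
#' @return An object of class `simulated_region`: list with `hapmat`,
#'   `genealogies` (one per segment), `segment` (segment index per SNV),
#'   `breakpoints`, `region`, and `seed`.
#' @export
simulate_region <- function(n_seq, n_snv, breakpoints = numeric(0),
                            region = c(1, 2e6), seed = NULL, max_tries = 100) {
  stopifnot(n_seq >= 2, n_snv >= 1, length(region) == 2, region[1] < region[2])
  if (length(breakpoints) > 0 &&
      (any(breakpoints <= region[1]) || any(breakpoints >= region[2])))
    stop("breakpoints must lie strictly inside the region", call. = FALSE)
  breakpoints <- sort(breakpoints)
  labels <- paste0("h", seq_len(n_seq))
  with_rng_seed(seed, {
    pos <- sort(sample.int(region[2] - region[1] + 1, n_snv)) + region[1] - 1
    segment <- findInterval(pos, breakpoints) + 1L
    n_seg <- length(breakpoints) + 1L

    for (try in seq_len(max_tries)) {
      genealogies <- vector("list", n_seg)
      mat <- matrix(0L, nrow = n_seq, ncol = n_snv)
      for (s in seq_len(n_seg)) {
        g <- simulate_genealogy(n_seq, labels = labels)
        genealogies[[s]] <- g
        cols <- which(segment == s)
        if (length(cols) > 0) {
          hm <- drop_mutations(g, length(cols), pos[cols])
          mat[, cols] <- hm$mat
        }
      }
      ok <- TRUE
      for (s in seq_len(n_seg - 1L)) {
        left <- which(segment == s); right <- which(segment == s + 1L)
        if (length(left) == 0 || length(right) == 0) next
        found <- FALSE
        for (i in left) {
          for (j in right) {
            if (!four_gamete_compatible(mat[, i], mat[, j])) { found <- TRUE; break }
          }
          if (found) break
        }
        if (!found) { ok <- FALSE; break }
      }
      if (ok) {
        hm <- hap_matrix(mat, snv_names = paste0("snv", seq_len(n_snv)),
                         hap_names = labels, pos = pos)
        return(structure(
          list(hapmat = hm, genealogies = genealogies, segment = segment,
               breakpoints = breakpoints, region = region, seed = seed),
          class = "simulated_region"
        ))
      }
    }
    stop("could not realize an incompatible SNV pair across every breakpoint in ",
         max_tries, " tries; use more SNVs or sequences per segment", call. = FALSE)
  })
}

#' @export
print.simulated_region <- function(x, ...) {
  cat("simulated_region:", nrow(x$hapmat$mat), "sequences,",
      ncol(x$hapmat$mat), "SNVs,", length(x$breakpoints), "breakpoints\n")
  invisible(x)
}

#' Simulate a binary phenotype driven by causal SNVs in a subregion
#'
#' Each sequence's affection probability is
#' `plogis(intercept + effect * c)` with `c` its count of derived alleles at
#' the causal SNVs (those inside `causal_window`). The default intercept
#' centers the linear predictor at the sample mean count, giving roughly
#' balanced phenotypes. The phenotypic distance matrix is the 0/1 mismatch
#' indicator between sequences.
#'
#' @param sim A `simulated_region` from [simulate_region()].
#' @param causal_window Length-2 base-pair interval containing the causal
#'   SNVs; must overlap at least one SNV.
#' @param effect Log-odds increase per causal derived allele (0 = null).
#' @param seed Optional RNG seed.
#' @param intercept Baseline log-odds; default `-effect * mean(count)`.
#' @return List with `phenotype` (named 0/1 vector), `dist` (mismatch
#'   distance matrix), `causal_indices` (column indices of causal SNVs),
#'   `effect`, and `intercept`.
#' @export
simulate_phenotype <- function(sim, causal_window = c(950e3, 1050e3),
                               effect = 2, seed = NULL, intercept = NULL) {
  stopifnot(inherits(sim, "simulated_region"), length(causal_window) == 2)
  pos <- sim$hapmat$pos
  causal <- which(pos >= causal_window[1] & pos <= causal_window[2])
  if (length(causal) == 0)
    stop("causal window [", causal_window[1], ", ", causal_window[2],
         "] bp contains no SNV", call. = FALSE)
  count <- rowSums(sim$hapmat$mat[, causal, drop = FALSE])
  if (is.null(intercept)) intercept <- -effect * mean(count)
  prob <- stats::plogis(intercept + effect * count)
  y <- with_rng_seed(seed, stats::rbinom(length(prob), 1, prob))
  names(y) <- sim$hapmat$hap_names
  d <- 1 * outer(y, y, "!=")
  dimnames(d) <- list(names(y), names(y))
  list(phenotype = y, dist = d, causal_indices = causal,
       effect = effect, intercept = intercept)
}
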