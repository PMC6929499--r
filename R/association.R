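# Region-wide association between reconstructed partitions and a comparator,
# with an omnibus permutation test. The omnibus statistic is the maximum of
# the per-focal-SNV profile (the standard scan statistic); only the
# comparator side is permuted, so the dependence structure among the
# reconstructed trees is held fixed under the null.

with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

perm_pvalue <- function(obs_max, perm_max) {
  # add-one (Phipson-Smyth style) estimate; never exactly zero
  (1 + sum(perm_max >= obs_max)) / (length(perm_max) + 1)
}

new_profile <- function(scan, statistic, values, p_value, nperm, seed, k = NULL) {
  structure(
    data.frame(snv_name = scan$snv_names, pos_bp = scan$pos,
               stat = values, stringsAsFactors = FALSE),
    statistic = statistic, p_value = p_value, nperm = nperm, seed = seed, k = k,
    class = c("association_profile", "data.frame")
  )
}

#' @export
print.association_profile <- function(x, ...) {
  cat("association_profile:", attr(x, "statistic"), "over", nrow(x), "focal SNVs\n")
  i <- which.max(x$stat)
  cat("max", format(x$stat[i], digits = 4), "at", x$snv_name[i],
      sprintf("(%s bp)\n", format(x$pos_bp[i], big.mark = ",")))
  if (!is.null(attr(x, "p_value")))
    cat("omnibus p =", format(attr(x, "p_value"), digits = 4),
        sprintf("(%d permutations, seed %s)\n", attr(x, "nperm"),
                format(attr(x, "seed"))))
  invisible(x)
}

#' Plot an association profile along the region
#'
#' @param x An `association_profile`.
#' @param markers Optional base-pair positions drawn as vertical dashed lines
#'   (e.g. the comparator position or a causal subregion's limits).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.association_profile <- function(x, markers = NULL, ...) {
  graphics::plot(x$pos_bp, x$stat, type = "b", pch = 20,
                 xlab = "position (bp)", ylab = attr(x, "statistic"), ...)
  if (!is.null(markers)) graphics::abline(v = markers, lty = 2, col = "red")
  invisible(x)
}

#' Write an association profile to CSV
#'
#' Columns `snv_name, pos_bp, statistic, value`; the omnibus p-value, nperm
#' and seed are recorded in `#`-prefixed header comment lines.
#' @param x An `association_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# statistic: ", attr(x, "statistic")), con)
  if (!is.null(attr(x, "p_value"))) {
    writeLines(c(paste0("# omnibus_p: ", attr(x, "p_value")),
                 paste0("# nperm: ", attr(x, "nperm")),
                 paste0("# seed: ", format(attr(x, "seed")))), con)
  }
  writeLines("snv_name,pos_bp,statistic,value", con)
  writeLines(paste(x$snv_name, format(x$pos_bp, scientific = FALSE, trim = TRUE),
                   attr(x, "statistic"), x$stat, sep = ","), con)
  invisible(path)
}

#' Rand-index association between reconstructed and comparator partitions
#'
#' For each reconstructed tree in the scan, both the tree and the comparator
#' are reduced to `k` clusters ([cut_clusters()]) and compared by the Rand
#' index. The comparator may be a `partition_tree` (cut to the same `k`) or a
#' ready-made named cluster assignment (used as-is). With `nperm > 0` an
#' omnibus permutation test of any association across the region is run: the
#' comparator's sequence labels are permuted, the whole profile recomputed,
#' and the observed profile maximum compared with the permuted maxima
#' (add-one p-value). The default `nperm = 0` skips testing.
#'
#' Trees with fewer than `k` tips (over-collapsed windows) fall back to their
#' own tip partition, with a warning.
#'
#' @param scan A `region_scan` from [reconstruct_region()].
#' @param comparator A `partition_tree` or a named cluster-id vector covering
#'   the same sequences.
#' @param k Number of clusters for the Rand-index comparison.
#' @param nperm Number of label permutations (0 = no test).
#' @param seed Optional RNG seed for the permutations.
#' @return An `association_profile` with one Rand index per focal SNV.
#' @export
test_rand_association <- function(scan, comparator, k, nperm = 0, seed = NULL) {
  stopifnot(inherits(scan, "region_scan"))
  if (inherits(comparator, "partition_tree")) {
    if (k > n_tips(comparator))
      stop("comparator tree has fewer than k tips", call. = FALSE)
    comp <- cut_clusters(comparator, k)
  } else {
    comp <- comparator
    if (is.null(names(comp)))
      stop("comparator partition must be a named cluster-id vector", call. = FALSE)
  }
  if (!setequal(names(comp), scan$hap_names))
    stop("comparator does not cover the scanned sequences; missing: ",
         paste(utils::head(setdiff(scan$hap_names, names(comp)), 5), collapse = ", "),
         call. = FALSE)

  cuts <- lapply(scan$trees, function(tr) {
    if (n_tips(tr) < k) {
      warning("tree at ", attr(tr, "window")$focal_name, " has only ",
              n_tips(tr), " tips; using its tip partition", call. = FALSE)
      cut_clusters(tr, n_tips(tr))
    } else {
      cut_clusters(tr, k)
    }
  })
  observed <- vapply(cuts, function(cl) rand_index(cl, comp), numeric(1))

  p_value <- NULL
  if (nperm > 0) {
    nm <- names(comp)
    perm_max <- with_rng_seed(seed, {
      vapply(seq_len(nperm), function(b) {
        bp <- comp
        names(bp) <- nm[sample(length(nm))]
        max(vapply(cuts, function(cl) rand_index(cl, bp), numeric(1)))
      }, numeric(1))
    })
    p_value <- perm_pvalue(max(observed), perm_max)
  }
  new_profile(scan, "RandIndex", observed, p_value, nperm, seed, k = k)
}

#' Distance-matrix association between reconstructed partitions and a comparator
#'
#' For each reconstructed tree, the rank-based distance matrix
#' ([rank_distance_matrix()]) is compared with the comparator distance matrix
#' `cdmat` using the chosen statistic: distance correlation (`"dCor"`),
#' Heller-Heller-Gorfine (`"HHG"`), Mantel, or RV. Method names are matched
#' case-insensitively. With `nperm > 0`, the omnibus permutation test jointly
#' permutes the rows and columns of `cdmat` (relabelling the comparator's
#' sequences), recomputes the full profile each time, and compares profile
#' maxima (add-one p-value).
#'
#' A focal SNV whose tree is fully collapsed (single tip, all-zero distances)
#' yields `NA` for Mantel and 0 for the other statistics; `NA`s are excluded
#' from the profile maximum.
#'
#' @param scan A `region_scan` from [reconstruct_region()].
#' @param cdmat Comparator pairwise distance matrix with the scanned sequence
#'   names as dimnames (e.g. phenotypic distances, or rank distances of a
#'   comparator dendrogram).
#' @param method One of `"dCor"`, `"HHG"`, `"Mantel"`, `"RV"`.
#' @param nperm Number of permutations for the omnibus test (0 = no test).
#' @param seed Optional RNG seed for the permutations.
#' @return An `association_profile` with one statistic value per focal SNV.
#' @export
test_distance_association <- function(scan, cdmat, method = c("dCor", "HHG", "Mantel", "RV"),
                                      nperm = 0, seed = NULL) {
  stopifnot(inherits(scan, "region_scan"))
  canonical <- c(dcor = "dCor", hhg = "HHG", mantel = "Mantel", rv = "RV")
  key <- tolower(if (length(method) > 1) method[1] else method)
  if (!key %in% names(canonical))
    stop("unknown method '", method[1], "'; valid options are dCor, HHG, Mantel, RV",
         call. = FALSE)
  method <- canonical[[key]]
  check_dist(cdmat, "cdmat")
  if (is.null(rownames(cdmat)))
    stop("cdmat must carry sequence names as dimnames", call. = FALSE)
  if (!setequal(rownames(cdmat), scan$hap_names))
    stop("cdmat does not cover the scanned sequences; missing: ",
         paste(utils::head(setdiff(scan$hap_names, rownames(cdmat)), 5), collapse = ", "),
         call. = FALSE)
  cdmat <- cdmat[scan$hap_names, scan$hap_names, drop = FALSE]

  rdists <- lapply(scan$trees, rank_distance_matrix)
  core <- switch(method,
    dCor = dcor_profile_core(rdists),
    Mantel = mantel_profile_core(rdists),
    RV = rv_profile_core(rdists),
    HHG = hhg_profile_core(rdists)
  )
  observed <- core(cdmat)

  p_value <- NULL
  if (nperm > 0) {
    n <- nrow(cdmat)
    obs_max <- max(observed, na.rm = TRUE)
    perm_max <- with_rng_seed(seed, {
      vapply(seq_len(nperm), function(b) {
        pm <- sample(n)
        max(core(cdmat[pm, pm, drop = FALSE]), na.rm = TRUE)
      }, numeric(1))
    })
    p_value <- perm_pvalue(obs_max, perm_max)
  }
  new_profile(scan, method, observed, p_value, nperm, seed)
}

# Profile "cores" precompute everything that depends only on the reconstructed
# trees, so each permutation costs one pass over the comparator. Each core
# takes an aligned comparator matrix (dimnames already in scan order; joint
# row/column permutations keep all statistics well-defined because centering
# commutes with relabelling).

dcor_profile_core <- function(rdists) {
  cent <- lapply(rdists, dcor_center)
  dvar1 <- vapply(cent, function(a) mean(a * a), numeric(1))
  stack <- do.call(rbind, lapply(cent, as.vector))
  n2 <- ncol(stack)
  function(cd) {
    b <- dcor_center(cd)
    dvar2 <- mean(b * b)
    if (dvar2 == 0) return(rep(0, nrow(stack)))
    dcov2 <- as.vector(stack %*% as.vector(b)) / n2
    out <- sqrt(pmax(dcov2, 0) / sqrt(dvar1 * dvar2))
    out[dvar1 == 0] <- 0
    out
  }
}

mantel_profile_core <- function(rdists) {
  u <- upper.tri(rdists[[1]])
  tri <- do.call(rbind, lapply(rdists, function(d) d[u]))
  mu <- rowMeans(tri)
  ctri <- tri - mu
  ss <- sqrt(rowSums(ctri^2))
  function(cd) {
    v <- cd[u]
    cv <- v - mean(v)
    sv <- sqrt(sum(cv^2))
    if (sv == 0) return(rep(NA_real_, nrow(tri)))
    r <- as.vector(ctri %*% cv) / (ss * sv)
    r[ss == 0] <- NA_real_
    r
  }
}

rv_profile_core <- function(rdists) {
  s1 <- lapply(rdists, gower_center)
  norm1 <- vapply(s1, function(s) sum(s * s), numeric(1))
  stack <- do.call(rbind, lapply(s1, as.vector))
  function(cd) {
    s2 <- gower_center(cd)
    norm2 <- sum(s2 * s2)
    if (norm2 == 0) return(rep(NA_real_, nrow(stack)))
    out <- as.vector(stack %*% as.vector(s2)) / sqrt(norm1 * norm2)
    out[norm1 == 0] <- 0
    out
  }
}

hhg_profile_core <- function(rdists) {
  function(cd) {
    vapply(rdists, function(d) hhg_core(d, cd), numeric(1))
  }
}
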