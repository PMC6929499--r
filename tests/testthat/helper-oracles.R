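# Independent brute-force oracles and small fixture builders. Each oracle is
# written from the defining formula, independently of the package's
# implementation path.

# Four-gamete test by exhaustive enumeration of observed 2-bit patterns.
oracle_fgt <- function(a, b) {
  length(unique(paste0(a, b))) < 4
}

# Rand index by enumerating all sequence pairs.
oracle_rand <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

# Mantel: Pearson correlation of upper triangles, from the raw definition.
oracle_mantel <- function(d1, d2) {
  d2 <- d2[rownames(d1), rownames(d1)]
  v1 <- d1[upper.tri(d1)]
  v2 <- d2[upper.tri(d2)]
  m1 <- mean(v1); m2 <- mean(v2)
  sum((v1 - m1) * (v2 - m2)) /
    sqrt(sum((v1 - m1)^2) * sum((v2 - m2)^2))
}

# RV: explicit Gower centering with the projector matrix.
oracle_rv <- function(d1, d2) {
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  J <- diag(n) - matrix(1, n, n) / n
  S1 <- -0.5 * J %*% (d1 * d1) %*% J
  S2 <- -0.5 * J %*% (d2 * d2) %*% J
  sum(diag(S1 %*% S2)) / sqrt(sum(diag(S1 %*% S1)) * sum(diag(S2 %*% S2)))
}

# dCor: textbook double-centering with explicit loops.
oracle_dcor <- function(d1, d2) {
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  center <- function(d) {
    a <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      a[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
    a
  }
  A <- center(d1); B <- center(d2)
  dcov2 <- sum(A * B) / n^2
  dvar1 <- sum(A * A) / n^2
  dvar2 <- sum(B * B) / n^2
  if (dvar1 == 0 || dvar2 == 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvar1 * dvar2))
}

# HHG: literal triple loop over (i, j, k).
oracle_hhg <- function(d1, d2) {
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  total <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    a11 <- a12 <- a21 <- a22 <- 0
    for (k in 1:n) {
      if (k == i || k == j) next
      in1 <- d1[i, k] <= d1[i, j]
      in2 <- d2[i, k] <= d2[i, j]
      if (in1 && in2) a11 <- a11 + 1
      else if (in1) a12 <- a12 + 1
      else if (in2) a21 <- a21 + 1
      else a22 <- a22 + 1
    }
    r1 <- a11 + a12; r2 <- a21 + a22; c1 <- a11 + a21; c2 <- a12 + a22
    if (r1 > 0 && r2 > 0 && c1 > 0 && c2 > 0)
      total <- total + (n - 2) * (a11 * a22 - a12 * a21)^2 / (r1 * r2 * c1 * c2)
  }
  total
}

# Random Euclidean distance matrix over named points.
random_dist <- function(n, names = paste0("s", seq_len(n))) {
  pts <- matrix(rnorm(2 * n), n, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(names, names)
  d
}

# Rank distances by walking every root-to-tip path of the flat tree:
# for each pair of sequences find the deepest node containing both, read the
# depth of the node at which their paths diverge.
oracle_rank_dist <- function(tree) {
  n <- length(tree$hap_names)
  path_to_tip <- function(tip_id) {
    path <- tip_id
    while (tree$parent[path[1]] != 0) path <- c(tree$parent[path[1]], path)
    path
  }
  tip_of <- integer(n)
  for (t in tree$tips) tip_of[tree$members[[t]]] <- t
  L <- max(vapply(tree$tips, function(t) length(path_to_tip(t)) - 1L, 1L))
  d <- matrix(0, n, n, dimnames = list(tree$hap_names, tree$hap_names))
  if (L == 0) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (tip_of[i] == tip_of[j]) next
      pi <- path_to_tip(tip_of[i]); pj <- path_to_tip(tip_of[j])
      shared <- 0
      while (shared < min(length(pi), length(pj)) &&
             pi[shared + 1] == pj[shared + 1]) shared <- shared + 1
      r <- shared  # depth of separating node + 1 = (shared - 1) + 1
      d[i, j] <- d[j, i] <- (L - r + 1) / L
    }
  }
  d
}

# Bipartition (split) set of a tree given as an ape phylo, as canonical
# strings over the smaller side of each split.
phylo_split_set <- function(ph) {
  tips <- sort(ph$tip.label)
  n <- length(tips)
  splits <- character(0)
  for (node in (n + 1):(n + ph$Nnode)) {
    below <- ape::extract.clade(ph, node)$tip.label
    a <- sort(below); b <- sort(setdiff(tips, below))
    if (length(a) == 0 || length(b) == 0) next
    key <- if (length(a) < length(b) || (length(a) == length(b) &&
                                         paste(a, collapse = ",") < paste(b, collapse = ",")))
      paste(a, collapse = ",") else paste(b, collapse = ",")
    splits <- c(splits, key)
  }
  sort(unique(splits))
}

# Canonical split set straight from a partition_tree's flat node table.
tree_split_set <- function(tree) {
  tips <- sort(vapply(tree$tips, function(t) tree$label[t], ""))
  labels_of <- function(id) {
    tip_ids <- tree$tips[vapply(tree$tips, function(t) {
      all(tree$members[[t]] %in% tree$members[[id]])
    }, logical(1))]
    sort(tree$label[tip_ids])
  }
  internal <- which(!is.na(tree$rank))
  splits <- character(0)
  for (id in internal) {
    a <- labels_of(id); b <- sort(setdiff(tips, a))
    if (length(a) == 0 || length(b) == 0) next
    key <- if (length(a) < length(b) || (length(a) == length(b) &&
                                         paste(a, collapse = ",") < paste(b, collapse = ",")))
      paste(a, collapse = ",") else paste(b, collapse = ",")
    splits <- c(splits, key)
  }
  sort(unique(splits))
}

# Small deterministic hap_matrix fixture.
toy_hapmat <- function() {
  m <- matrix(c(0, 0, 1, 0,
                1, 0, 0, 0,
                1, 1, 0, 1,
                1, 1, 0, 1), nrow = 4, byrow = TRUE)
  hap_matrix(m, snv_names = paste0("snv", 1:4),
             hap_names = paste0("h", 1:4),
             pos = c(1000, 2000, 3000, 4000))
}
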