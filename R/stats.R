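# Association statistics between two partitions or two distance matrices.
# All statistics are invariant to a simultaneous reordering of sequences in
# both inputs; callers align inputs by name before dispatch.

align_by_names <- function(d1, d2) {
  n1 <- rownames(d1); n2 <- rownames(d2)
  if (is.null(n1) || is.null(n2))
    stop("distance matrices must carry sequence names as dimnames", call. = FALSE)
  if (!setequal(n1, n2)) {
    miss <- setdiff(n1, n2)
    extra <- setdiff(n2, n1)
    stop("distance matrices cover different sequences",
         if (length(miss)) paste0("; missing: ", paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  d2[n1, n1, drop = FALSE]
}

check_dist <- function(d, arg = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(arg, " must be a square matrix", call. = FALSE)
  invisible(d)
}

#' Rand index between two cluster assignments
#'
#' The proportion of sequence pairs on which the two partitions agree:
#' clustered together in both, or apart in both, out of all `choose(n, 2)`
#' pairs. Equals 1 iff the partitions are identical.
#'
#' @param a,b Named cluster-id vectors (e.g. from [cut_clusters()]) over the
#'   same sequence names.
#' @return Rand index in `[0, 1]`.
#' @examples
#' rand_index(c(s1 = 1, s2 = 1, s3 = 2, s4 = 2),
#'            c(s1 = 1, s2 = 2, s3 = 1, s4 = 2)) # 1/3
#' @export
rand_index <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("cluster assignments must be named", call. = FALSE)
  if (!setequal(names(a), names(b)))
    stop("cluster assignments cover different sequences", call. = FALSE)
  b <- b[names(a)]
  n <- length(a)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  tab <- table(a, b)
  npairs <- choose(n, 2)
  disagreements <- (sum(rowSums(tab)^2) + sum(colSums(tab)^2) - 2 * sum(tab^2)) / 2
  (npairs - disagreements) / npairs
}

#' Mantel statistic between two distance matrices
#'
#' Pearson correlation of the vectorized strict upper triangles after
#' aligning the matrices by sequence name.
#'
#' @param d1,d2 Symmetric distance matrices with matching dimnames.
#' @return Correlation in `[-1, 1]`.
#' @export
mantel_stat <- function(d1, d2) {
  check_dist(d1); check_dist(d2)
  d2 <- align_by_names(d1, d2)
  u <- upper.tri(d1)
  v1 <- d1[u]; v2 <- d2[u]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("Mantel statistic undefined: constant upper triangle", call. = FALSE)
  stats::cor(v1, v2)
}

gower_center <- function(d) {
  d2 <- d^2
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  -0.5 * j %*% d2 %*% j
}

#' RV coefficient between two distance matrices
#'
#' Each matrix is converted to a cross-product (similarity) matrix by the
#' Gower transform of its squared distances, `S = -1/2 J D^2 J` with J the
#' centering projector; then `RV = tr(S1 S2) / sqrt(tr(S1^2) tr(S2^2))`.
#' Scale-invariant: `rv_coefficient(D, c * D) = 1` for any `c > 0`.
#'
#' @param d1,d2 Symmetric distance matrices with matching dimnames.
#' @return RV coefficient in `[0, 1]`.
#' @export
rv_coefficient <- function(d1, d2) {
  check_dist(d1); check_dist(d2)
  d2 <- align_by_names(d1, d2)
  s1 <- gower_center(d1)
  s2 <- gower_center(d2)
  den <- sqrt(sum(s1 * s1) * sum(s2 * s2))
  if (den == 0)
    stop("RV coefficient undefined: degenerate (all-zero) configuration", call. = FALSE)
  sum(s1 * s2) / den
}

dcor_center <- function(d) {
  rm <- rowMeans(d); cm <- colMeans(d); gm <- mean(d)
  sweep(sweep(d, 1, rm), 2, cm) + gm
}

#' Distance correlation between two distance matrices
#'
#' The sample distance correlation computed directly from the two matrices:
#' each is double-centered (row means, column means, grand mean removed),
#' `dCov^2` is the mean elementwise product of the centered matrices, and
#' `dCor = dCov / (dVar1 dVar2)^(1/2)` with the convention `dCor = 0` when
#' either distance variance is zero. For matrices that are not exact
#' Euclidean distance matrices `dCov^2` can be slightly negative; it is
#' clamped at zero.
#'
#' @param d1,d2 Symmetric distance matrices with matching dimnames.
#' @return Distance correlation in `[0, 1]`; 0 for degenerate input.
#' @export
dcor_stat <- function(d1, d2) {
  check_dist(d1); check_dist(d2)
  d2 <- align_by_names(d1, d2)
  a <- dcor_center(d1)
  b <- dcor_center(d2)
  dvar1 <- mean(a * a)
  dvar2 <- mean(b * b)
  if (dvar1 == 0 || dvar2 == 0) return(0)
  dcov2 <- mean(a * b)
  sqrt(max(dcov2, 0) / sqrt(dvar1 * dvar2))
}

#' Heller-Heller-Gorfine statistic between two distance matrices
#'
#' For every ordered pair (i, j), i != j, the remaining points k are
#' cross-classified by whether `d1(i,k) <= d1(i,j)` and whether
#' `d2(i,k) <= d2(i,j)` (ties inclusive); the Pearson chi-square statistic of
#' each 2x2 table is summed over pairs. Tables with a zero margin contribute
#' 0. Sensitive to general (non-monotone) dependence between the two
#' distance structures.
#'
#' @param d1,d2 Symmetric distance matrices with matching dimnames, n >= 3.
#' @return Nonnegative sum of chi-square statistics.
#' @export
hhg_stat <- function(d1, d2) {
  check_dist(d1); check_dist(d2)
  d2 <- align_by_names(d1, d2)
  hhg_core(d1, d2)
}

# Vectorized over k for each (i, j): counts come from the inclusion matrices
# M[k, j] = d(i, k) <= d(i, j); k = i and k = j always land in the (<=, <=)
# cell (d(i,i) = 0 and d(i,j) <= d(i,j)), so both are removed from that cell
# and from its margins.
hhg_core <- function(d1, d2) {
  n <- nrow(d1)
  if (n < 3) stop("HHG statistic needs at least 3 sequences", call. = FALSE)
  m <- n - 2
  total <- 0
  for (i in seq_len(n)) {
    m1 <- outer(d1[i, ], d1[i, ], "<=")
    m2 <- outer(d2[i, ], d2[i, ], "<=")
    a11 <- colSums(m1 & m2) - 2
    r1 <- colSums(m1) - 2
    c1 <- colSums(m2) - 2
    a12 <- r1 - a11
    a21 <- c1 - a11
    a22 <- m - a11 - a12 - a21
    r2 <- m - r1; c2 <- m - c1
    keep <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
    keep[i] <- FALSE
    if (!any(keep)) next
    total <- total + sum(m * (a11[keep] * a22[keep] - a12[keep] * a21[keep])^2 /
                           (r1[keep] * r2[keep] * c1[keep] * c2[keep]))
  }
  total
}
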