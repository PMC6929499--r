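#' Four-gamete compatibility of two SNV columns
#'
#' Under the infinite-sites model with no recombination, two diallelic sites
#' are compatible with a single mutational history unless all four haplotype
#' patterns 00, 01, 10, 11 are observed across sequences, in which case one
#' site must have mutated twice (or recombination occurred).
#'
#' @param a,b Equal-length 0/1 vectors (two SNV columns over the same
#'   sequences).
#' @return `FALSE` iff all four gametes occur (the pair is incompatible);
#'   `TRUE` otherwise.
#' @examples
#' four_gamete_compatible(c(0, 0, 1, 1), c(0, 1, 0, 1)) # FALSE
#' four_gamete_compatible(c(0, 0, 1, 1), c(0, 0, 1, 1)) # TRUE
#' @export
four_gamete_compatible <- function(a, b) {
  if (length(a) != length(b))
    stop("columns have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  !(any(a == 0 & b == 0) && any(a == 0 & b == 1) &&
    any(a == 1 & b == 0) && any(a == 1 & b == 1))
}

#' Default minimum window size
#'
#' The minimum number of SNVs in the neighborhood around a focal SNV defaults
#' to the larger of one and 2% of the total number of SNVs, rounded up.
#'
#' @param total_snvs Total number of SNVs in the haplotype matrix.
#' @return `max(1, ceiling(0.02 * total_snvs))`.
#' @examples
#' default_min_window(2747) # 55
#' default_min_window(20)   # 1
#' @export
default_min_window <- function(total_snvs) {
  if (length(total_snvs) != 1 || is.na(total_snvs) || total_snvs < 1)
    stop("total_snvs must be a positive integer", call. = FALSE)
  max(1L, as.integer(ceiling(0.02 * total_snvs)))
}

#' Select the SNV neighborhood around a focal SNV
#'
#' Starting at the focal SNV, the window is grown one column at a time to the
#' left and to the right, keeping each adjacent SNV while it passes the
#' four-gamete test against the focal column; each side stops just before the
#' first incompatible SNV. If the resulting window holds fewer than
#' `min_window` SNVs, the not-yet-included SNV adjacent to the window whose
#' base-pair distance to the focal SNV is smallest is appended (ties go left),
#' repeatedly, until the minimum size is reached or the region is exhausted.
#' Padding SNVs are classified as incompatible for ordering purposes, even
#' when they individually pass the four-gamete test against the focal column,
#' because they lie beyond the first incompatibility boundary.
#'
#' @param x A [hap_matrix()] object.
#' @param focal Column index of the focal SNV.
#' @param min_window Minimum neighborhood size; default
#'   [default_min_window()] of the SNV count.
#' @return An object of class `snv_neighborhood`: list with `focal`, `lower`,
#'   `upper` (inclusive column indices), `lower_pos`, `upper_pos`,
#'   `compatible` (indices, unordered), and `incompatible` (padding indices).
#' @export
select_neighborhood <- function(x, focal, min_window = default_min_window(ncol(x$mat))) {
  stopifnot(inherits(x, "hap_matrix"))
  p <- ncol(x$mat)
  if (length(focal) != 1 || is.na(focal) || focal < 1 || focal > p)
    stop("focal SNV index must be in 1..", p, call. = FALSE)
  focal <- as.integer(focal)
  if (min_window < 1) stop("min_window must be >= 1", call. = FALSE)

  fc <- x$mat[, focal]
  lo <- focal
  while (lo > 1 && four_gamete_compatible(fc, x$mat[, lo - 1L])) lo <- lo - 1L
  hi <- focal
  while (hi < p && four_gamete_compatible(fc, x$mat[, hi + 1L])) hi <- hi + 1L
  compatible <- lo:hi
  incompatible <- integer(0)

  target <- min(min_window, p)
  fpos <- x$pos[focal]
  while ((hi - lo + 1L) < target) {
    left_ok <- lo > 1L
    right_ok <- hi < p
    take_left <- if (left_ok && right_ok) {
      dl <- abs(x$pos[lo - 1L] - fpos)
      dr <- abs(x$pos[hi + 1L] - fpos)
      dl <= dr   # equidistant -> left (smaller position) first
    } else left_ok
    if (take_left) {
      lo <- lo - 1L
      incompatible <- c(incompatible, lo)
    } else {
      hi <- hi + 1L
      incompatible <- c(incompatible, hi)
    }
  }

  structure(
    list(focal = focal, lower = lo, upper = hi,
         lower_pos = x$pos[lo], upper_pos = x$pos[hi],
         compatible = compatible, incompatible = incompatible),
    class = "snv_neighborhood"
  )
}

#' @export
print.snv_neighborhood <- function(x, ...) {
  cat("SNV neighborhood around focal column", x$focal, "\n")
  cat("  window columns:", x$lower, "-", x$upper,
      sprintf("(%s - %s bp)\n",
              format(x$lower_pos, big.mark = ","),
              format(x$upper_pos, big.mark = ",")))
  cat("  compatible:", length(x$compatible),
      " padding (incompatible):", length(x$incompatible), "\n")
  invisible(x)
}

#' Order the SNVs of a neighborhood for recursive partitioning
#'
#' Compatible SNVs are ordered from most ancient to most recent using allele
#' age inferred from the derived-allele frequency: under the infinite-sites
#' model, older mutations have had more time to drift upward in frequency, so
#' SNVs are sorted by decreasing frequency of the derived (coded-1) allele.
#' For the common case of derived frequencies below one half this coincides
#' with sorting by decreasing minor allele frequency, the observable proxy
#' when ancestral states are unknown; using the derived-allele frequency
#' directly keeps the age ranking correct for old variants that have drifted
#' above frequency 0.5, which in turn guarantees that on recombination-free
#' infinite-sites data every split's derived-carrier set is a clade of the
#' underlying genealogy. Incompatible (padding) SNVs follow, ordered by
#' increasing physical distance to the focal SNV. Ties in frequency are
#' broken by physical proximity to the focal SNV, then by column index; ties
#' in distance by column index.
#'
#' @param x A [hap_matrix()] object.
#' @param nbhd A neighborhood from [select_neighborhood()] on `x`.
#' @return Integer vector of column indices: age-ordered compatible SNVs
#'   followed by proximity-ordered incompatible SNVs.
#' @export
order_neighborhood <- function(x, nbhd) {
  stopifnot(inherits(x, "hap_matrix"), inherits(nbhd, "snv_neighborhood"))
  fpos <- x$pos[nbhd$focal]
  comp <- nbhd$compatible
  daf <- colMeans(x$mat[, comp, drop = FALSE])
  dist <- abs(x$pos[comp] - fpos)
  comp_ord <- comp[order(-daf, dist, comp)]
  inc <- nbhd$incompatible
  if (length(inc) > 0) {
    dinc <- abs(x$pos[inc] - fpos)
    inc_ord <- inc[order(dinc, inc)]
  } else inc_ord <- integer(0)
  c(comp_ord, inc_ord)
}
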