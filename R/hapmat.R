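#' Construct a haplotype matrix object
#'
#' A `hap_matrix` holds a sample of phased binary sequences: a 0/1 matrix with
#' one row per haplotype and one column per diallelic SNV, together with
#' sequence names, SNV names, and the physical position (base pairs) of each
#' SNV. Allele 1 is the derived (ALT) allele; allele 0 is ancestral.
#'
#' Positions must be strictly increasing: the compatibility-window logic
#' assumes sorted, distinct positions, so ties are rejected rather than broken
#' silently. Monomorphic columns are permitted (they never split a cluster and
#' are not filtered at load).
#'
#' @param mat Integer or numeric matrix of 0s and 1s, sequences in rows and
#'   SNVs in columns.
#' @param snv_names Character vector of distinct SNV labels, one per column.
#' @param hap_names Character vector of distinct sequence labels, one per row.
#' @param pos Numeric vector of physical positions in base pairs, one per
#'   column, strictly increasing.
#'
#' @return An object of class `hap_matrix`: a list with elements `mat`,
#'   `hap_names`, `snv_names`, and `pos`. The matrix carries the names as
#'   dimnames.
#'
#' @examples
#' m <- matrix(c(0, 1, 0, 1,
#'               0, 0, 1, 1,
#'               1, 1, 0, 0,
#'               1, 0, 1, 0), nrow = 4, byrow = TRUE)
#' hap_matrix(m, snv_names = paste0("snv", 1:4),
#'            hap_names = paste0("h", 1:4),
#'            pos = c(1000, 2000, 3000, 4000))
#' @export
hap_matrix <- function(mat, snv_names, hap_names, pos) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  snv_names <- as.character(snv_names)
  hap_names <- as.character(hap_names)
  pos <- as.numeric(pos)

  bad <- which(!(mat == 0L | mat == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "haplotype matrix must contain only 0/1 entries; first offending entry at row %d, column %d (value %s)",
      bad[1, 1], bad[1, 2], format(mat[bad[1, 1], bad[1, 2]])
    ), call. = FALSE)
  }
  if (length(hap_names) != nrow(mat))
    stop("length(hap_names) must equal the number of rows (",
         length(hap_names), " vs ", nrow(mat), ")", call. = FALSE)
  if (length(snv_names) != ncol(mat))
    stop("length(snv_names) must equal the number of columns (",
         length(snv_names), " vs ", ncol(mat), ")", call. = FALSE)
  if (length(pos) != ncol(mat))
    stop("length(pos) must equal the number of columns (",
         length(pos), " vs ", ncol(mat), ")", call. = FALSE)
  if (anyNA(pos)) stop("positions must not contain NA", call. = FALSE)
  if (ncol(mat) > 1 && any(diff(pos) <= 0))
    stop("positions must be strictly increasing (duplicate or unsorted position near index ",
         which(diff(pos) <= 0)[1] + 1, ")", call. = FALSE)
  if (anyDuplicated(hap_names))
    stop("duplicated sequence names: ",
         paste(unique(hap_names[duplicated(hap_names)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(snv_names))
    stop("duplicated SNV names: ",
         paste(unique(snv_names[duplicated(snv_names)]), collapse = ", "),
         call. = FALSE)

  dimnames(mat) <- list(hap_names, snv_names)
  structure(
    list(mat = mat, hap_names = hap_names, snv_names = snv_names, pos = pos),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", nrow(x$mat), "sequences x", ncol(x$mat), "SNVs\n")
  cat("positions:", format(x$pos[1], big.mark = ","), "-",
      format(x$pos[length(x$pos)], big.mark = ","), "bp\n")
  n <- min(6L, nrow(x$mat)); p <- min(10L, ncol(x$mat))
  print(x$mat[seq_len(n), seq_len(p), drop = FALSE])
  if (nrow(x$mat) > n || ncol(x$mat) > p) cat("...\n")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$mat)

#' Write a haplotype matrix to a delimited text file
#'
#' The format is plain CSV (or any single-character delimiter): a header row
#' `hap,<snv names...>`, a second row `pos,<positions...>`, then one row per
#' sequence with its name followed by its 0/1 alleles. [read_hap_matrix()]
#' reads this format back bit-exactly.
#'
#' @param x A [hap_matrix()] object.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_hap_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "hap_matrix"))
  lines <- c(
    paste(c("hap", x$snv_names), collapse = sep),
    paste(c("pos", format(x$pos, scientific = FALSE, trim = TRUE)), collapse = sep),
    vapply(seq_along(x$hap_names), function(i) {
      paste(c(x$hap_names[i], x$mat[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a haplotype matrix from a delimited text file
#'
#' Expects the layout written by [write_hap_matrix()]: a header row of SNV
#' names, a `pos` row of base-pair positions, then one 0/1 row per sequence.
#'
#' @param path Input file path.
#' @param sep Field delimiter (default comma).
#' @return A validated [hap_matrix()] object.
#' @export
read_hap_matrix <- function(path, sep = ",") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3)
    stop("file '", path, "' does not contain a header, a position row, and at least one sequence",
         call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged) > 0)
    stop("ragged row in '", path, "' at line ", ragged[1],
         " (", lengths(fields)[ragged[1]], " fields, expected ", width, ")",
         call. = FALSE)
  snv_names <- fields[[1]][-1]
  if (tolower(fields[[2]][1]) != "pos")
    stop("second line must be the position row (starting with 'pos')", call. = FALSE)
  pos <- suppressWarnings(as.numeric(fields[[2]][-1]))
  if (anyNA(pos)) stop("non-numeric position in '", path, "'", call. = FALSE)
  body <- fields[-(1:2)]
  hap_names <- vapply(body, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.integer(f[-1]), integer(width - 1L))
  )
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = 1L)
  if (anyNA(mat)) stop("non-integer allele value in '", path, "'", call. = FALSE)
  hap_matrix(mat, snv_names = snv_names, hap_names = hap_names, pos = pos)
}

#' Build a haplotype matrix from a phased VCF file
#'
#' Reads a VCF restricted to phased, diallelic records with no missing
#' genotypes. Each diploid sample contributes two rows named `<sample>_1` and
#' `<sample>_2` (first and second haplotype of the phased GT field). Allele 1
#' in the matrix is the ALT allele. Positions come from POS (1-based); SNV
#' names from ID, or `<chrom>:<pos>` when ID is ".". Records are sorted by
#' position.
#'
#' @param path Path to a VCF (v4.x) file, plain text or bgzipped.
#' @return A validated [hap_matrix()] object.
#' @export
hapmat_from_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no records", call. = FALSE)
  chrom <- fix[, "CHROM"]
  if (length(unique(chrom)) > 1)
    stop("VCF spans multiple chromosomes (", paste(unique(chrom), collapse = ", "),
         "); a compatibility window is defined on a single chromosome", call. = FALSE)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | alt == "." | is.na(alt)
  if (any(multi))
    stop("record at position ", fix[which(multi)[1], "POS"],
         " is not strictly diallelic (ALT = '", alt[which(multi)[1]], "')",
         call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  if (anyNA(gt) || any(gt == "." | gt == "./." | gt == ".|."))
    stop("missing genotype in VCF; the method requires complete data", call. = FALSE)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype ('/' separator) found; the method requires phased data",
         call. = FALSE)
  if (!all(grepl("^[01]\\|[01]$", gt)))
    stop("genotypes must be phased diploid 0|0, 0|1, 1|0 or 1|1", call. = FALSE)

  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))

  pos <- as.numeric(fix[, "POS"])
  id <- fix[, "ID"]
  snv_names <- ifelse(is.na(id) | id == ".", paste0(chrom, ":", fix[, "POS"]), id)
  ord <- order(pos)

  # interleave: sample1_1, sample1_2, sample2_1, ...
  mat <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(fix))
  mat[seq(1, nrow(mat), by = 2), ] <- t(a1)
  mat[seq(2, nrow(mat), by = 2), ] <- t(a2)
  hap_names <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))

  hap_matrix(mat[, ord, drop = FALSE],
             snv_names = snv_names[ord], hap_names = hap_names, pos = pos[ord])
}

#' Write a haplotype matrix as a phased diploid VCF
#'
#' Consecutive row pairs (1,2), (3,4), ... form pseudo-diploid samples, so the
#' file round-trips through [hapmat_from_vcf()]: row `2i-1` becomes haplotype
#' `_1` and row `2i` haplotype `_2` of sample `i`. Requires an even number of
#' sequences. REF/ALT are written as A/T placeholders (only the GT field
#' carries information here).
#'
#' @param x A [hap_matrix()] with an even number of rows.
#' @param path Output path for the plain-text VCF.
#' @param chrom Chromosome label to write (default `"1"`).
#' @param sample_names Optional sample names (default `sample1`, ...).
#' @return Invisibly, `path`.
#' @export
write_hapmat_vcf <- function(x, path, chrom = "1", sample_names = NULL) {
  stopifnot(inherits(x, "hap_matrix"))
  n <- nrow(x$mat)
  if (n %% 2 != 0)
    stop("need an even number of sequences to form pseudo-diploid samples", call. = FALSE)
  ns <- n %/% 2
  if (is.null(sample_names)) sample_names <- paste0("sample", seq_len(ns))
  stopifnot(length(sample_names) == ns)

  gt <- vapply(seq_len(ns), function(s) {
    paste0(x$mat[2 * s - 1, ], "|", x$mat[2 * s, ])
  }, character(ncol(x$mat)))
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = ncol(x$mat))

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(x$mat)), function(j) {
    paste(c(chrom, format(x$pos[j], scientific = FALSE, trim = TRUE),
            x$snv_names[j], "A", "T", ".", "PASS", ".", "GT", gt[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
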