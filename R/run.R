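# Config-driven entry points binding the modules into reproducible runs.
# Each run writes its outputs plus a JSON manifest (package version, config,
# seed) sufficient to reproduce it. A thin command-line wrapper over these
# functions ships in inst/scripts/dendroscan.

load_input_hapmat <- function(config) {
  path <- config$input
  if (is.null(path)) stop("config$input is required", call. = FALSE)
  fmt <- config$format
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  switch(fmt,
    vcf = hapmat_from_vcf(path),
    table = read_hap_matrix(path, sep = if (is.null(config$delim)) "," else config$delim),
    stop("unknown input format '", fmt, "' (use 'vcf' or 'table')", call. = FALSE)
  )
}

resolve_focal <- function(x, focal) {
  if (is.character(focal)) {
    i <- match(focal, x$snv_names)
    if (is.na(i)) stop("no SNV named '", focal, "'", call. = FALSE)
    return(i)
  }
  as.integer(focal)
}

write_manifest <- function(out_dir, command, config) {
  manifest <- list(
    package = "dendroscan",
    version = as.character(utils::packageVersion("dendroscan")),
    command = command,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Run a reconstruction from a configuration list
#'
#' Loads a haplotype matrix, reconstructs either the single-focal-SNV tree or
#' all trees in a (sub)region, and writes Newick output plus per-focal window
#' reports and a manifest to `config$out_dir`.
#'
#' Recognized config fields: `input`, `format` ("vcf"/"table"), `delim`,
#' `focal` (column number or SNV name; omit for region mode), `from`/`to`
#' (subregion bounds in bp, inclusive), `min_window` (number or "default"),
#' `sep`, `out_dir`.
#'
#' @param config Named list (see Details).
#' @return Invisibly, the reconstructed `partition_tree` or `region_scan`.
#' @export
run_reconstruct <- function(config) {
  x <- load_input_hapmat(config)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mw <- config$min_window
  if (is.null(mw) || identical(mw, "default")) mw <- default_min_window(ncol(x$mat))
  sep <- if (is.null(config$sep)) "-" else config$sep

  if (!is.null(config$focal)) {
    tree <- reconstruct_partition(x, resolve_focal(x, config$focal),
                                  min_window = mw, sep = sep)
    writeLines(to_newick(tree), file.path(out_dir, "tree.nwk"))
    writeLines(window_report(tree, x), file.path(out_dir, "window.txt"))
    result <- tree
  } else {
    scan <- reconstruct_region(x, min_window = mw, sep = sep,
                               from = config$from, to = config$to)
    writeLines(vapply(scan$trees, to_newick, character(1)),
               file.path(out_dir, "trees.nwk"))
    reports <- unlist(lapply(scan$trees, function(tr) c(window_report(tr, x), "")))
    writeLines(reports, file.path(out_dir, "windows.txt"))
    result <- scan
  }
  write_manifest(out_dir, "reconstruct", config)
  invisible(result)
}

#' Run an association scan from a configuration list
#'
#' Reconstructs trees across the region of the input haplotype matrix and
#' tests them against a comparator distance matrix (CSV, for
#' dCor/HHG/Mantel/RV) or a comparator partition (two-column CSV
#' `name,cluster`, for the Rand index). Writes the profile CSV and a
#' manifest; prints the omnibus p-value when `nperm > 0`.
#'
#' Additional config fields over [run_reconstruct()]: `method` (one of dCor,
#' HHG, Mantel, RV, RandIndex), `comparator` (path), `k` (clusters, Rand
#' only), `nperm`, `seed`.
#'
#' @param config Named list (see Details).
#' @return Invisibly, the `association_profile`.
#' @export
run_associate <- function(config) {
  x <- load_input_hapmat(config)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mw <- config$min_window
  if (is.null(mw) || identical(mw, "default")) mw <- default_min_window(ncol(x$mat))
  sep <- if (is.null(config$sep)) "-" else config$sep
  nperm <- if (is.null(config$nperm)) 0 else config$nperm
  if (nperm > 0 && is.null(config$seed))
    stop("a seed is required when nperm > 0", call. = FALSE)

  scan <- reconstruct_region(x, min_window = mw, sep = sep,
                             from = config$from, to = config$to)
  method <- if (is.null(config$method)) "dCor" else config$method
  if (tolower(method) %in% c("randindex", "rand", "ri")) {
    comp_df <- utils::read.csv(config$comparator, stringsAsFactors = FALSE)
    comp <- stats::setNames(as.integer(factor(comp_df[[2]])), comp_df[[1]])
    k <- if (is.null(config$k)) length(unique(comp)) else config$k
    profile <- test_rand_association(scan, comp, k = k, nperm = nperm,
                                     seed = config$seed)
  } else {
    cdmat <- read_distance_matrix(config$comparator)
    profile <- test_distance_association(scan, cdmat, method = method,
                                         nperm = nperm, seed = config$seed)
  }
  write_profile(profile, file.path(out_dir, "profile.csv"))
  if (!is.null(attr(profile, "p_value")))
    message("omnibus p-value: ", format(attr(profile, "p_value")))
  write_manifest(out_dir, "associate", config)
  invisible(profile)
}

#' Run a simulation from a configuration list
#'
#' Simulates a region ([simulate_region()]) and optionally a phenotype
#' ([simulate_phenotype()]); writes the haplotype matrix (delimited and, for
#' an even number of sequences, VCF), the true per-segment genealogies as
#' Newick, the phenotype table, and a manifest. Byte-identical outputs for
#' the same config and seed.
#'
#' Config fields: `n_seq`, `n_snv`, `breakpoints` (bp vector), `region`
#' (length-2 bp), `causal_window` (length-2 bp; omit for no phenotype),
#' `effect`, `seed`, `out_dir`.
#'
#' @param config Named list (see Details).
#' @return Invisibly, the `simulated_region`.
#' @export
run_simulate <- function(config) {
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$seed)) stop("config$seed is required for simulation", call. = FALSE)
  sim <- simulate_region(
    n_seq = config$n_seq, n_snv = config$n_snv,
    breakpoints = if (is.null(config$breakpoints)) numeric(0) else config$breakpoints,
    region = if (is.null(config$region)) c(1, 2e6) else config$region,
    seed = config$seed
  )
  write_hap_matrix(sim$hapmat, file.path(out_dir, "haplotypes.csv"))
  if (nrow(sim$hapmat$mat) %% 2 == 0)
    write_hapmat_vcf(sim$hapmat, file.path(out_dir, "haplotypes.vcf"))
  writeLines(vapply(sim$genealogies, genealogy_newick, character(1)),
             file.path(out_dir, "true_genealogies.nwk"))
  if (!is.null(config$causal_window)) {
    ph <- simulate_phenotype(sim, causal_window = config$causal_window,
                             effect = if (is.null(config$effect)) 2 else config$effect,
                             seed = config$seed + 1)
    utils::write.csv(
      data.frame(hap = names(ph$phenotype), phenotype = ph$phenotype,
                 row.names = NULL),
      file.path(out_dir, "phenotype.csv"), quote = FALSE, row.names = FALSE
    )
    write_distance_matrix(ph$dist, file.path(out_dir, "phenotype_dist.csv"))
  }
  write_manifest(out_dir, "simulate", config)
  invisible(sim)
}
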