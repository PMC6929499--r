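Package: dendroscan
Title: Local Perfect-Phylogeny Reconstruction and Association Scans for
    Binary Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the local perfect phylogeny (a recursive
    partition of phased binary haplotypes) around each focal
    single-nucleotide variant, using four-gamete compatibility to grow a
    window of sites and minor-allele-frequency ordering to drive the
    recursive partitioning. Reconstructed partitions across a genomic
    region can be compared with a user-supplied partition, dendrogram, or
    pairwise distance matrix (for example phenotypic distances) through
    the Rand index, distance correlation, Heller-Heller-Gorfine, Mantel,
    and RV statistics, with a region-wide omnibus permutation p-value.
    Includes a seeded coalescent-style simulator (infinite-sites
    mutations on random genealogies, optional recombination breakpoints,
    binary phenotypes driven by causal variants) used throughout the test
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
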