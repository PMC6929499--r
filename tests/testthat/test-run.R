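test_that("run_simulate writes reloadable, seed-stable outputs with a manifest", {
  out1 <- withr::local_tempdir()
  cfg <- list(n_seq = 10, n_snv = 20, breakpoints = 1e6, seed = 42,
              causal_window = c(9e5, 1.1e6), out_dir = out1)
  sim <- run_simulate(cfg)
  expect_true(file.exists(file.path(out1, "haplotypes.csv")))
  expect_true(file.exists(file.path(out1, "haplotypes.vcf")))
  expect_true(file.exists(file.path(out1, "true_genealogies.nwk")))
  expect_true(file.exists(file.path(out1, "phenotype.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  back <- read_hap_matrix(file.path(out1, "haplotypes.csv"))
  expect_identical(back$mat, sim$hapmat$mat)
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$config$seed, 42L)

  out2 <- withr::local_tempdir()
  cfg$out_dir <- out2
  run_simulate(cfg)
  expect_identical(readLines(file.path(out1, "haplotypes.csv")),
                   readLines(file.path(out2, "haplotypes.csv")))
  expect_identical(readLines(file.path(out1, "phenotype.csv")),
                   readLines(file.path(out2, "phenotype.csv")))
})

test_that("run_reconstruct handles single-focal, region, and subregion modes", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim")
  run_simulate(list(n_seq = 10, n_snv = 20, seed = 5, out_dir = sim_dir))
  input <- file.path(sim_dir, "haplotypes.csv")

  single <- file.path(dir, "single")
  tr <- run_reconstruct(list(input = input, focal = 3, out_dir = single))
  expect_s3_class(tr, "partition_tree")
  nwk <- readLines(file.path(single, "tree.nwk"))
  expect_length(nwk, 1L)
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
  expect_true(any(grepl("^focal_snv: snv3$", readLines(file.path(single, "window.txt")))))

  # focal SNV addressable by name as well as by column number
  byname <- run_reconstruct(list(input = input, focal = "snv3",
                                 out_dir = file.path(dir, "byname")))
  expect_identical(to_newick(byname), to_newick(tr))

  region <- file.path(dir, "region")
  scan <- run_reconstruct(list(input = input, out_dir = region))
  expect_length(scan, 20L)
  expect_length(readLines(file.path(region, "trees.nwk")), 20L)

  x <- read_hap_matrix(input)
  subr <- run_reconstruct(list(input = input, from = x$pos[5], to = x$pos[9],
                               out_dir = file.path(dir, "sub")))
  expect_length(subr, 5L)
})

test_that("run_reconstruct accepts VCF input", {
  dir <- withr::local_tempdir()
  run_simulate(list(n_seq = 8, n_snv = 10, seed = 15, out_dir = dir))
  tr <- run_reconstruct(list(input = file.path(dir, "haplotypes.vcf"),
                             focal = 1, out_dir = file.path(dir, "out")))
  expect_s3_class(tr, "partition_tree")
  expect_equal(length(tr$hap_names), 8L)
})

test_that("run_associate produces a profile CSV and a seeded omnibus p-value", {
  dir <- withr::local_tempdir()
  run_simulate(list(n_seq = 12, n_snv = 15, seed = 33,
                    causal_window = c(5e5, 1.5e6), out_dir = dir))
  cfg <- list(input = file.path(dir, "haplotypes.csv"),
              comparator = file.path(dir, "phenotype_dist.csv"),
              method = "RV", min_window = 2, nperm = 19, seed = 7,
              out_dir = file.path(dir, "assoc"))
  prof <- run_associate(cfg)
  expect_s3_class(prof, "association_profile")
  expect_equal(nrow(prof), 15L)
  expect_false(is.null(attr(prof, "p_value")))

  cfg$out_dir <- file.path(dir, "assoc2")
  prof2 <- run_associate(cfg)
  expect_identical(attr(prof, "p_value"), attr(prof2, "p_value"))

  # nperm = 0 emits no p-value; nperm > 0 without a seed is rejected
  cfg$nperm <- 0; cfg$out_dir <- file.path(dir, "assoc3")
  expect_null(attr(run_associate(cfg), "p_value"))
  cfg$nperm <- 5; cfg$seed <- NULL
  expect_error(run_associate(cfg), "seed")
})

test_that("run_associate supports Rand-index mode with a partition CSV", {
  dir <- withr::local_tempdir()
  sim <- run_simulate(list(n_seq = 10, n_snv = 12, seed = 44, out_dir = dir))
  scan <- reconstruct_region(sim$hapmat, min_window = 2)
  part <- cut_clusters(scan$trees[[4]], 3)
  comp_path <- file.path(dir, "comparator.csv")
  utils::write.csv(data.frame(hap = names(part), cluster = as.integer(part)),
                   comp_path, row.names = FALSE, quote = FALSE)
  prof <- run_associate(list(input = file.path(dir, "haplotypes.csv"),
                             comparator = comp_path, method = "RandIndex",
                             min_window = 2, k = 3,
                             out_dir = file.path(dir, "ri")))
  expect_equal(attr(prof, "statistic"), "RandIndex")
  expect_equal(prof$stat[4], 1)
})

test_that("the command-line wrapper drives simulate and reconstruct", {
  script <- system.file("scripts", "dendroscan", package = "dendroscan")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")

  st <- system2(rscript, c(script, "simulate", "--n-seq", "8", "--n-snv", "10",
                           "--seed", "3", "--out-dir", dir),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(dir, "haplotypes.csv")))

  st <- system2(rscript, c(script, "reconstruct", "--input",
                           file.path(dir, "haplotypes.csv"), "--focal", "2",
                           "--out-dir", file.path(dir, "rec")),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(dir, "rec", "tree.nwk")))

  # invalid input exits nonzero
  st <- system2(rscript, c(script, "reconstruct", "--input",
                           file.path(dir, "nope.csv"), "--focal", "1",
                           "--out-dir", dir),
                stdout = FALSE, stderr = FALSE)
  expect_gt(st, 0L)
})
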