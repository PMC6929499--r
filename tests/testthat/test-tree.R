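test_that("four distinct haplotypes over two SNVs give four singleton tips", {
  m <- matrix(c(0, 0,
                0, 1,
                1, 0,
                1, 1), nrow = 4, byrow = TRUE)
  x <- hap_matrix(m, c("sA", "sB"), paste0("h", 1:4), c(100, 200))
  tr <- build_partition(x, ordered_snvs = c(1, 2))
  expect_equal(n_tips(tr), 4L)
  expect_true(all(lengths(tr$members[tr$tips]) == 1))
  # every tip's allele vector over the window is unique (brute force)
  pats <- apply(m, 1, paste, collapse = "")
  expect_false(any(duplicated(pats)))
  # first split is by column 1 (rank 1), and splits are consistent with columns
  root_snv <- tr$snv_index[which(tr$rank == 1)]
  expect_equal(root_snv, 1L)
  for (id in which(!is.na(tr$rank))) {
    s <- tr$snv_index[id]
    expect_true(all(m[tr$members[[tr$child0[id]]], s] == 0))
    expect_true(all(m[tr$members[[tr$child1[id]]], s] == 1))
  }
})

test_that("indistinguishable sequences collapse into one sep-joined tip", {
  m <- matrix(c(0, 1,
                1, 0,
                0, 1), nrow = 3, byrow = TRUE)
  x <- hap_matrix(m, c("sA", "sB"), c("h1", "h2", "h3"), c(100, 200))
  tr <- build_partition(x, c(1, 2), sep = "-")
  expect_equal(n_tips(tr), 2L)
  expect_true("h1-h3" %in% tr$label[tr$tips])

  tr2 <- build_partition(x, c(1, 2), sep = "+")
  expect_true("h1+h3" %in% tr2$label[tr2$tips])
})

test_that("sequences identical over the whole window form a single-tip tree", {
  m <- matrix(0L, nrow = 3, ncol = 2)
  x <- hap_matrix(m, c("sA", "sB"), c("a", "b", "c"), c(10, 20))
  tr <- build_partition(x, c(1, 2))
  expect_equal(n_tips(tr), 1L)
  expect_equal(tr$label[tr$tips], "a-b-c")
  expect_equal(to_newick(tr), "(a-b-c);")
})

test_that("reconstruction records window limits; fully compatible data spans all", {
  sim <- simulate_region(n_seq = 8, n_snv = 10, seed = 3)
  tr <- reconstruct_partition(sim$hapmat, focal = 1, min_window = 1)
  w <- attr(tr, "window")
  expect_equal(w$lower_pos, sim$hapmat$pos[1])
  expect_equal(w$upper_pos, sim$hapmat$pos[10])
  expect_equal(w$focal_name, "snv1")
})

test_that("duplicated row groups appear as multi-sequence tips", {
  set.seed(7)
  base <- simulate_region(n_seq = 6, n_snv = 20, seed = 7)$hapmat
  m <- rbind(base$mat, base$mat[c(1, 2), ])  # duplicate two rows
  x <- hap_matrix(m, base$snv_names, c(base$hap_names, "d1", "d2"), base$pos)
  tr <- reconstruct_partition(x, focal = 5, min_window = 20)
  tip_holding <- function(nm) {
    which(vapply(tr$tips, function(t) nm %in% tr$hap_names[tr$members[[t]]],
                 logical(1)))
  }
  expect_equal(tip_holding("h1"), tip_holding("d1"))
  expect_equal(tip_holding("h2"), tip_holding("d2"))
  expect_true(length(tr$members[[tr$tips[tip_holding("h1")]]]) >= 2)
  # tips are exactly the identical-row classes over the window
  window_cols <- attr(tr, "window")$ordered_snvs
  pats <- apply(x$mat[, window_cols, drop = FALSE], 1, paste, collapse = "")
  expect_equal(n_tips(tr), length(unique(pats)))
})

test_that("a single polymorphic SNV splits the root into two tips", {
  x <- hap_matrix(matrix(c(0, 1, 1), 3, 1), "s", c("a", "b", "c"), 100)
  tr <- reconstruct_partition(x, focal = 1)
  expect_equal(n_tips(tr), 2L)
  expect_equal(sort(tr$label[tr$tips]), c("a", "b-c"))
  expect_equal(tr$snv_name[1], "s")
})

test_that("region scan returns one tree per focal SNV, bounds inclusive", {
  sim <- simulate_region(n_seq = 10, n_snv = 20, seed = 13)
  scan <- reconstruct_region(sim$hapmat, min_window = 2)
  expect_s3_class(scan, "region_scan")
  expect_length(scan, 20L)

  p <- sim$hapmat$pos
  sub <- reconstruct_region(sim$hapmat, min_window = 2, from = p[4], to = p[6])
  expect_length(sub, 3L)
  expect_equal(sub$focal_indices, 4:6)
  t_direct <- reconstruct_partition(sim$hapmat, focal = 4, min_window = 2)
  expect_identical(to_newick(sub$trees[[1]]), to_newick(t_direct))

  expect_error(reconstruct_region(sim$hapmat, from = max(p) + 1, to = max(p) + 2),
               "no focal SNVs")
  expect_error(reconstruct_region(sim$hapmat, from = 10, to = 5), "exceeds")
})

test_that("newick output re-parses to the identical topology and tip set", {
  for (seed in c(2, 9, 31)) {
    sim <- simulate_region(n_seq = 9, n_snv = 15, seed = seed)
    tr <- reconstruct_partition(sim$hapmat, focal = 8, min_window = 15)
    ph <- ape::read.tree(text = to_newick(tr))
    expect_setequal(ph$tip.label, tr$label[tr$tips])
    # bipartition sets agree (Robinson-Foulds distance 0)
    expect_identical(phylo_split_set(ph), tree_split_set(tr))
  }
})

test_that("reconstruction is deterministic", {
  sim <- simulate_region(n_seq = 10, n_snv = 20, seed = 17)
  t1 <- reconstruct_partition(sim$hapmat, focal = 10)
  t2 <- reconstruct_partition(sim$hapmat, focal = 10)
  expect_identical(to_newick(t1, annotate = TRUE), to_newick(t2, annotate = TRUE))
})

test_that("on fully compatible data every SNV's carriers are a union of subtrees", {
  for (seed in c(4, 8)) {
    sim <- simulate_region(n_seq = 10, n_snv = 12, seed = seed)
    x <- sim$hapmat
    tr <- reconstruct_partition(x, focal = 6, min_window = 12)
    carriers_ok <- function(id, carriers) {
      inter <- sum(tr$members[[id]] %in% carriers)
      if (inter == 0 || inter == length(tr$members[[id]])) return(TRUE)
      if (is.na(tr$child0[id])) return(FALSE)
      carriers_ok(tr$child0[id], carriers) && carriers_ok(tr$child1[id], carriers)
    }
    for (j in seq_len(ncol(x$mat))) {
      expect_true(carriers_ok(1L, which(x$mat[, j] == 1L)))
    }
  }
})

test_that("as_phylo returns an ape phylo with matching tips", {
  sim <- simulate_region(n_seq = 8, n_snv = 10, seed = 23)
  tr <- reconstruct_partition(sim$hapmat, focal = 3)
  ph <- as_phylo(tr)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, tr$label[tr$tips])
})
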