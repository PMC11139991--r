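test_that("fmeasure on frozen hand-computable partitions", {
  # partition identical to label classes
  expect_equal(fmeasure(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # two classes of 5, all ten sequences in one cluster: P=0.5, R=1 -> 2/3
  expect_equal(fmeasure(rep(1, 10), rep(c("a", "b"), each = 5)), 2 / 3)
  # two classes of 2, all singletons: P=1, R=0.5 -> 2/3
  expect_equal(fmeasure(1:4, c("a", "a", "b", "b")), 2 / 3)
  expect_error(fmeasure(integer(0), character(0)), "empty")
})

test_that("fmeasure agrees with direct P/R computation on enumerated partitions", {
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    labels <- sample(letters[1:3], n, replace = TRUE)
    clusters <- sample(1:4, n, replace = TRUE)
    expect_equal(fmeasure(clusters, labels),
                 oracle_fmeasure(clusters, labels))
  }
})

test_that("fmeasure is invariant to relabelling and order, 1 iff exact", {
  set.seed(8)
  labels <- sample(letters[1:4], 20, replace = TRUE)
  clusters <- sample(1:5, 20, replace = TRUE)
  f <- fmeasure(clusters, labels)
  perm <- sample(20)
  expect_equal(fmeasure(clusters[perm], labels[perm]), f)
  relab <- c(9, 3, 7, 1, 5)[clusters]
  expect_equal(fmeasure(relab, labels), f)
  expect_lt(fmeasure(clusters, labels), 1)
  expect_equal(fmeasure(as.integer(factor(labels)), labels), 1)
})

test_that("threshold optimization recovers the separating threshold", {
  set.seed(33)
  a <- 0.02; b <- 0.10
  for (rep in 1:20) {
    refs <- make_ref_set(n_taxa = 5, n_per = 3, a = a, b = b)
    d <- sparse_distances(refs[, c("id", "sequence")],
                          use_prefilter = FALSE)
    opt <- optimize_threshold(refs$id, refs$label, d, grid_step = 0.005)
    expect_true(opt$eligible)
    expect_equal(opt$fscore, 1)
    expect_gte(opt$threshold, 0) # smallest maximizer
    intra <- max(d$dist[sub("_r.*", "", d$id1) == sub("_r.*", "", d$id2)])
    expect_gte(opt$threshold + 0.005, intra) # at/above max intra distance
    expect_lt(opt$threshold, b)              # below the separation
  }
})

test_that("eligibility requires five subtaxa and ten references", {
  set.seed(9)
  refs <- make_ref_set(n_taxa = 4, n_per = 3, a = 0.02, b = 0.1)
  d <- sparse_distances(refs[, c("id", "sequence")], use_prefilter = FALSE)
  expect_false(optimize_threshold(refs$id, refs$label, d)$eligible)

  refs5 <- make_ref_set(n_taxa = 5, n_per = 1, a = 0.02, b = 0.1)
  d5 <- sparse_distances(refs5[, c("id", "sequence")], use_prefilter = FALSE)
  expect_false(optimize_threshold(refs5$id, refs5$label, d5)$eligible)

  one <- make_ref_set(n_taxa = 1, n_per = 12, a = 0.02, b = 0.1)
  d1 <- sparse_distances(one[, c("id", "sequence")], use_prefilter = FALSE)
  expect_false(optimize_threshold(one$id, one$label, d1)$eligible)
})

test_that("ties pick the smallest maximizing grid threshold", {
  # two taxa of five refs each, perfectly separable: F=1 already at t=0
  set.seed(12)
  refs <- make_ref_set(n_taxa = 5, n_per = 2, a = 0, b = 0.2)
  refs$sequence[seq(1, 9, 2)] <- refs$sequence[seq(2, 10, 2)] # identical
  d <- sparse_distances(refs[, c("id", "sequence")], use_prefilter = FALSE)
  opt <- optimize_threshold(refs$id, refs$label, d, grid_step = 0.01)
  expect_equal(opt$threshold, 0)
  expect_equal(opt$fscore, 1)
})

test_that("halving the grid step never decreases the best F", {
  set.seed(14)
  refs <- make_ref_set(n_taxa = 5, n_per = 3, a = 0.04, b = 0.08)
  d <- sparse_distances(refs[, c("id", "sequence")], use_prefilter = FALSE)
  f_coarse <- optimize_threshold(refs$id, refs$label, d,
                                 grid_step = 0.02)$fscore
  f_fine <- optimize_threshold(refs$id, refs$label, d,
                               grid_step = 0.01)$fscore
  expect_gte(f_fine, f_coarse)
})

test_that("threshold lookup walks the ancestor chain to the root", {
  tab <- tibble::tibble(
    supertaxon = c("Fungi", "Fungi", "OrdA", "GenB"),
    superrank = c("kingdom", "kingdom", "order", "genus"),
    subrank = c("species", "genus", "species", "species"),
    threshold = c(0.03, 0.05, 0.021, 0.017),
    fscore = 1, n_subtaxa = 6L, n_refs = 20L)
  class(tab) <- c("threshold_tbl", class(tab))
  lin <- c(kingdom = "Fungi", phylum = "PhyA", class = "ClsA",
           order = "OrdA", family = "FamB", genus = "GenB")
  # direct genus-level entry
  expect_equal(lookup_threshold(lin, "species", tab), 0.017)
  # genus/family lack entries, order has one
  lin2 <- replace(lin, "genus", "GenZ")
  expect_equal(lookup_threshold(lin2, "species", tab), 0.021)
  # nothing below the root
  lin3 <- c(kingdom = "Fungi", phylum = "PhyZ", class = "ClsZ",
            order = "OrdZ", family = "FamZ", genus = "GenZ")
  expect_equal(lookup_threshold(lin3, "species", tab), 0.03)
  # pseudotaxon labels are skipped on the way up
  lin4 <- replace(lin, c("order", "genus"),
                  c("pseudoorder_0001", "pseudogenus_0002"))
  expect_equal(lookup_threshold(lin4, "species", tab), 0.03)
  # no entry anywhere
  expect_error(lookup_threshold(lin3, "class", tab), "no threshold entry")
})

test_that("threshold tables round-trip through CSV", {
  b <- small_sim(seed = 3)
  d <- sparse_distances(b$sim$refs[, c("sh_id", "sequence")])
  tab <- build_threshold_table(b$sim$refs, d, grid_step = 0.01)
  expect_true(all(tab$n_subtaxa >= 5 & tab$n_refs >= 10))
  expect_true(all(tab$subrank != tab$superrank))
  f <- withr::local_tempfile(fileext = ".csv")
  write_threshold_table(tab, f)
  back <- read_threshold_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
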