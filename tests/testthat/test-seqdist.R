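test_that("dissimilarity follows the distance-table semantics", {
  # identical sequences
  expect_equal(pairwise_dissimilarity("ACGTACGTACGTACGTACGT",
                                      "ACGTACGTACGTACGTACGT"), 0)
  # identical except for a terminal gap
  expect_equal(pairwise_dissimilarity("ACGTT", "CGTT"), 0)
  # one substitution in ten aligned positions, no gaps
  expect_equal(pairwise_dissimilarity("ACGTACGTAC", "ACGTACGTAT"), 0.1)
  # one internal gap column in an otherwise identical pair
  expect_equal(pairwise_dissimilarity("ACGTACGTAC", "ACGTCGTAC"), 0.1)
  # symmetry
  a <- rand_seq(40); b <- rand_seq(40)
  expect_equal(pairwise_dissimilarity(a, b), pairwise_dissimilarity(b, a))
})

test_that("implementation matches the exhaustive alignment oracle", {
  set.seed(101)
  base <- rand_seq(50)
  seqs <- c(
    vapply(c(0.02, 0.05, 0.1, 0.2, 0.3, 0.5),
           function(r) mutate_at_rate(base, r), character(1)),
    substr(base, 4, 50),          # leading truncation
    substr(base, 1, 44),          # trailing truncation
    paste0(substr(base, 1, 20), substr(base, 25, 50)), # internal deletion
    vapply(1:4, function(i) rand_seq(50), character(1)),
    vapply(1:4, function(i) mutate_at_rate(base, 0.08), character(1))
  )
  ids <- sprintf("q%02d", seq_along(seqs))
  d <- sparse_distances(tibble::tibble(id = ids, sequence = seqs),
                        max_dist = 0.6, use_prefilter = FALSE)
  n <- length(seqs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      od <- oracle_dissim(seqs[i], seqs[j])
      row <- d[d$id1 == ids[i] & d$id2 == ids[j], ]
      if (od <= 0.6) {
        expect_equal(nrow(row), 1)
        expect_equal(row$dist, od, tolerance = 1e-12)
      } else {
        expect_equal(nrow(row), 0) # omitted pairs are exactly the far ones
      }
    }
  }
})

test_that("the k-mer prefilter never skips near pairs", {
  set.seed(7)
  base <- rand_seq(200)
  seqs <- vapply(c(0, 0.02, 0.05, 0.1, 0.15, 0.2),
                 function(r) mutate_at_rate(base, r), character(1))
  tb <- tibble::tibble(id = sprintf("s%d", seq_along(seqs)),
                       sequence = seqs)
  with_f <- sparse_distances(tb, use_prefilter = TRUE)
  without <- sparse_distances(tb, use_prefilter = FALSE)
  near <- without[without$dist <= 0.3, ]
  expect_equal(dplyr::anti_join(near, with_f, by = c("id1", "id2")) |> nrow(),
               0)
})

test_that("cutoff semantics omit distant pairs and store no self-pairs", {
  tb <- tibble::tibble(id = c("a", "b"),
                       sequence = c("AAAAAAAAAAAAAAAAAAAA",
                                    "CCCCCCCCCCCCCCCCCCCC"))
  d <- sparse_distances(tb, max_dist = 0.6, use_prefilter = FALSE)
  expect_equal(nrow(d), 0)
  d1 <- sparse_distances(tb[1, ], use_prefilter = FALSE)
  expect_equal(nrow(d1), 0)
  expect_error(sparse_distances(tb[0, ]), "no sequences")
})

test_that("end-gap duplicate collapse merges transitively and sums reads", {
  res <- collapse_end_gap_duplicates(
    tibble::tibble(asv_id = c("a", "b"), sequence = c("ACGTT", "CGTT"),
                   reads = c(10, 5)))
  expect_equal(res$asvs$asv_id, "a")
  expect_equal(res$asvs$sequence, "ACGTT")
  expect_equal(res$asvs$reads, 15)

  # no end-gap relation: unchanged
  res2 <- collapse_end_gap_duplicates(
    tibble::tibble(asv_id = c("a", "b"), sequence = c("ACGT", "TTTT"),
                   reads = c(3, 3)))
  expect_equal(nrow(res2$asvs), 2)

  # transitivity over nested suffixes
  res3 <- collapse_end_gap_duplicates(
    tibble::tibble(asv_id = c("a", "b", "c"),
                   sequence = c("ACGTT", "CGTT", "GTT"),
                   reads = c(10, 5, 1)))
  expect_equal(nrow(res3$asvs), 1)
  expect_equal(res3$asvs$reads, 16)
  expect_equal(res3$asvs$sequence, "ACGTT")

  # representative is the most abundant member, total reads conserved
  set.seed(3)
  base <- rand_seq(60)
  tb <- tibble::tibble(
    asv_id = c("x", "y", "z", "w"),
    sequence = c(base, substr(base, 5, 60), mutate_at_rate(base, 0.3),
                 substr(base, 1, 50)),
    reads = c(2, 9, 4, 1))
  res4 <- collapse_end_gap_duplicates(tb)
  expect_equal(sum(res4$asvs$reads), sum(tb$reads))
  merged <- res4$map$representative[res4$map$asv_id == "x"]
  expect_equal(merged, "y") # y has the most reads in its merge class
})

test_that("nearest reference returns the closest hit within the cutoff", {
  refs <- tibble::tibble(id = c("r1", "r2"),
                         sequence = c("ACGTACGTACGTACGTACGT",
                                      "ACGTACGTACGTACGTACTT"))
  hit <- nearest_reference(
    tibble::tibble(id = "q", sequence = "ACGTACGTACGTACGTACGT"),
    refs, max_dissimilarity = 0.2, use_prefilter = FALSE)
  expect_equal(hit$ref_id, "r1")
  expect_equal(hit$dist, 0)

  none <- nearest_reference(
    tibble::tibble(id = "q", sequence = "GGGGGGGGGGGGGGGGGGGG"),
    refs, max_dissimilarity = 0.2, use_prefilter = FALSE)
  expect_true(is.na(none$ref_id))

  # brute-force check over a larger reference set
  set.seed(21)
  base <- rand_seq(80)
  refs2 <- tibble::tibble(id = sprintf("r%02d", 1:12),
                          sequence = vapply(
                            c(0.05, 0.15, seq(0.02, 0.5, length.out = 10)),
                            function(r) mutate_at_rate(base, r),
                            character(1)))
  q <- tibble::tibble(id = "q", sequence = base)
  hit2 <- nearest_reference(q, refs2, max_dissimilarity = 0.2,
                            use_prefilter = FALSE)
  brute <- vapply(refs2$sequence,
                  function(s) oracle_dissim(base, s), numeric(1))
  best <- min(brute)
  expect_equal(hit2$dist, best)
  expect_equal(hit2$ref_id,
               min(refs2$id[abs(brute - best) < 1e-12]))
})
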