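mk_dist <- function(...) {
  e <- list(...)
  df <- tibble::tibble(
    id1 = vapply(e, `[[`, character(1), 1),
    id2 = vapply(e, `[[`, character(1), 2),
    dist = vapply(e, function(x) as.numeric(x[[3]]), numeric(1)))
  swap <- df$id1 > df$id2
  tmp <- df$id1[swap]; df$id1[swap] <- df$id2[swap]; df$id2[swap] <- tmp
  attr(df, "max_dist") <- 0.6
  class(df) <- c("sparse_dist", class(df))
  df
}

test_that("cores form per distinct confident taxon", {
  asg <- tibble::tibble(
    asv_id = c("a", "b", "c", "d"),
    rank = "genus",
    taxon = c("GenA", "GenA", "GenB", "GenA"),
    prob = c(0.95, 0.92, 0.91, 0.85))
  cores <- form_cores(asg, "genus")
  expect_equal(sort(cores$asv_id), c("a", "b", "c")) # d below 0.90
  expect_equal(dplyr::n_distinct(cores$taxon), 2)    # cores never merged
})

test_that("closed-reference assignment chains to a fixed point", {
  # B is within t of the core, C only of B: two iterations
  d <- mk_dist(list("A", "B", 0.02), list("B", "C", 0.02),
               list("A", "C", 0.5))
  res <- closed_reference_assign(tibble::tibble(asv_id = "A", label = "X"),
                                 c("B", "C"), d, threshold = 0.03)
  expect_setequal(res$clusters$asv_id, c("A", "B", "C"))
  expect_equal(unique(res$clusters$label), "X")
  expect_equal(res$unassigned, character(0))
  expect_equal(res$clusters$recruited[res$clusters$asv_id != "A"],
               c(TRUE, TRUE))
})

test_that("an ASV near two cores joins only the closer one", {
  d <- mk_dist(list("z", "X1", 0.01), list("z", "Y1", 0.02))
  res <- closed_reference_assign(
    tibble::tibble(asv_id = c("X1", "Y1"), label = c("X", "Y")),
    "z", d, threshold = 0.03)
  expect_equal(res$clusters$label[res$clusters$asv_id == "z"], "X")
  expect_equal(dplyr::n_distinct(res$clusters$label), 2)
})

test_that("ASVs beyond the threshold stay unassigned", {
  d <- mk_dist(list("A", "u", 0.5))
  res <- closed_reference_assign(tibble::tibble(asv_id = "A", label = "X"),
                                 "u", d, threshold = 0.03)
  expect_equal(res$unassigned, "u")
})

test_that("single-core expansion equals the single-linkage component", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    ids <- sprintf("v%02d", 1:n)
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < 0.12
    d <- tibble::tibble(id1 = ids[pairs[keep, 1]],
                        id2 = ids[pairs[keep, 2]],
                        dist = stats::runif(sum(keep), 0, 0.1))
    attr(d, "max_dist") <- 0.6
    class(d) <- c("sparse_dist", class(d))
    t0 <- 0.05
    core <- ids[1]
    res <- closed_reference_assign(
      tibble::tibble(asv_id = core, label = "X"),
      setdiff(ids, core), d, threshold = t0)
    comp <- oracle_components(ids, d, t0)
    expect_setequal(res$clusters$asv_id, ids[comp == comp[core]])
  }
})

test_that("de novo clustering yields brute-force connected components", {
  d <- mk_dist(list("A", "B", 0.02), list("B", "C", 0.02),
               list("A", "C", 0.5), list("D", "E", 0.01))
  res <- denovo_cluster(c("A", "B", "C", "D", "E", "F"), d, 0.03, "genus")
  got <- setNames(res$clusters$label, res$clusters$asv_id)
  expect_equal(unname(got["A"]), unname(got["B"]))
  expect_equal(unname(got["B"]), unname(got["C"]))
  expect_equal(unname(got["D"]), unname(got["E"]))
  expect_equal(dplyr::n_distinct(got), 3)
  comp <- oracle_components(c("A", "B", "C", "D", "E", "F"), d, 0.03)
  expect_equal(dplyr::n_distinct(got), dplyr::n_distinct(comp))
})

test_that("pseudotaxon names continue a zero-padded counter", {
  d <- mk_dist(list("A", "B", 0.01))
  res <- denovo_cluster(c("A", "B"), d, 0.03, "genus", counter = 215L)
  expect_equal(unique(res$clusters$label), "pseudogenus_0216")
  expect_equal(res$counter, 216L)
})

root_thresholds <- function(t = 0.1) {
  tab <- tidyr::expand_grid(supertaxon = "Fungi", superrank = "kingdom",
                            subrank = cluster_ranks())
  tab$threshold <- t; tab$fscore <- 1
  tab$n_subtaxa <- 6L; tab$n_refs <- 20L
  class(tab) <- c("threshold_tbl", class(tab))
  tab
}

test_that("a single unassigned ASV becomes a fully pseudo-labelled OTU", {
  asvs <- tibble::tibble(asv_id = "a1", sequence = "ACGTACGT", reads = 5)
  asg <- tibble::tibble(asv_id = character(0), rank = character(0),
                        taxon = character(0), prob = numeric(0))
  d <- mk_dist()[0, ]
  attr(d, "max_dist") <- 0.6
  class(d) <- c("sparse_dist", class(d))
  h <- cluster_all_ranks(asvs, asg, d, root_thresholds())
  expect_equal(nrow(h$otus), 1)
  expect_true(all(is_pseudo(unlist(h$otus[, cluster_ranks()]))))
  expect_equal(h$otus$sequence, "ACGTACGT")
})

test_that("ASVs in different assigned phyla never share lower pseudotaxa", {
  # two ASVs, confidently placed in different phyla, sequence distance far
  # below every threshold
  asvs <- tibble::tibble(asv_id = c("a", "b"),
                         sequence = c("ACGTACGTACGT", "ACGTACGTACGA"),
                         reads = c(1, 1))
  asg <- tibble::tibble(asv_id = c("a", "b"), rank = "phylum",
                        taxon = c("PhyA", "PhyB"), prob = 0.99)
  d <- mk_dist(list("a", "b", 0.05))
  h <- cluster_all_ranks(asvs, asg, d, root_thresholds(t = 0.2))
  m <- tidy(h)
  expect_equal(dplyr::n_distinct(m$phylum), 2)
  for (r in c("class", "order", "family", "genus", "species")) {
    expect_equal(dplyr::n_distinct(m[[r]]), 2)
  }
})

test_that("synthetic species with perfect assignments give one OTU each", {
  b <- small_sim(seed = 19, unassigned_fraction = 0, partial_fraction = 0,
                 nonfungal_species = 0L, n_unknown_asvs = 0L,
                 end_gap_fraction = 0)
  res <- run_pipeline(b$data, b$sim$refs, out_dir = NULL)
  truth <- b$data$truth
  m <- tidy(res$hierarchy) |>
    dplyr::inner_join(truth, by = "asv_id")
  per_species <- m |>
    dplyr::summarise(n_otu = dplyr::n_distinct(.data$otu_id),
                     .by = "true_otu")
  expect_true(all(per_species$n_otu == 1))
  expect_equal(nrow(res$hierarchy$otus),
               dplyr::n_distinct(truth$species[truth$origin == "fungal"]))
})

test_that("hierarchy refines, preserves cores and is order-invariant", {
  b <- small_sim(seed = 23)
  d <- b$data
  dist_asv <- sparse_distances(d$asvs[, c("asv_id", "sequence")])
  ref_dist <- sparse_distances(b$sim$refs[, c("sh_id", "sequence")])
  thr <- build_threshold_table(b$sim$refs, ref_dist, grid_step = 0.005)
  h <- cluster_all_ranks(d$asvs, d$assignments, dist_asv, thr)
  m <- tidy(h)

  # refinement: the partition at each rank nests inside the rank above
  ranks <- cluster_ranks()
  for (i in 2:length(ranks)) {
    parents <- m |>
      dplyr::distinct(.data[[ranks[i]]], .data[[ranks[i - 1]]])
    expect_equal(anyDuplicated(parents[[1]]), 0)
  }

  # core preservation: at least one cluster per confident taxon
  for (r in ranks) {
    conf <- d$assignments[d$assignments$rank == r &
                            d$assignments$prob >= 0.9 &
                            d$assignments$asv_id %in% m$asv_id, ]
    expect_gte(dplyr::n_distinct(m[[r]]), dplyr::n_distinct(conf$taxon))
  }

  # determinism under permuted input order
  set.seed(1)
  perm <- sample(nrow(d$asvs))
  h2 <- cluster_all_ranks(d$asvs[perm, ],
                          d$assignments[sample(nrow(d$assignments)), ],
                          dist_asv, thr)
  expect_equal(tidy(h2), m)
  expect_equal(h2$otus, h$otus)
})
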