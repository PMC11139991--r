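mk_refs <- function() {
  set.seed(31)
  tibble::tibble(
    sh_id = c("SH1", "SH2", "SH3"),
    sequence = c(rand_seq(60), rand_seq(60), rand_seq(60)),
    kingdom = c("Fungi", "Viridiplantae", "unspecified"),
    phylum = c("PhyF", "PhyV", NA), class = NA_character_,
    order = NA_character_, family = NA_character_, genus = NA_character_,
    species = c("SpF", "SpV", NA))
}

test_that("kingdom classification follows the best-hit rule", {
  refs <- mk_refs()
  asvs <- tibble::tibble(
    asv_id = c("a1", "a2", "a3", "a4"),
    sequence = c(refs$sequence[1],                    # identical to Fungi
                 mutate_at_rate(refs$sequence[2], 0.1), # plant at ~0.1
                 rand_seq(60),                        # no hit
                 refs$sequence[3]))                   # unspecified hit
  calls <- classify_kingdom(asvs, refs, use_prefilter = FALSE)
  expect_equal(calls$status,
               c("known_fungi", "known_nonfungi", "unknown", "unknown"))
  expect_equal(calls$dist[1], 0)
  expect_true(is.na(calls$sh_id[3]))
  expect_equal(calls$kingdom[2], "Viridiplantae")
})

mk_hier <- function(labels_by_rank, otu_of = NULL) {
  ids <- names(labels_by_rank[[1]])
  mem <- tibble::tibble(asv_id = ids, kingdom = "Fungi")
  for (r in cluster_ranks()) {
    mem[[r]] <- unname(labels_by_rank[[r]][ids])
    mem[[paste0("prov_", r)]] <- "denovo"
  }
  mem$otu_id <- if (is.null(otu_of)) mem$species else unname(otu_of[ids])
  otus <- mem |>
    dplyr::distinct(.data$otu_id, .keep_all = TRUE) |>
    dplyr::transmute(.data$otu_id, kingdom = "Fungi", .data$phylum,
                     .data$class, .data$order, .data$family, .data$genus,
                     .data$species, rep_asv = .data$asv_id,
                     sequence = "ACGT")
  structure(list(membership = mem, otus = otus, counters = NULL),
            class = "cluster_hierarchy")
}

same_all_ranks <- function(ids, label) {
  l <- setNames(rep(label, length(ids)), ids)
  setNames(rep(list(l), 6), cluster_ranks())
}

mk_calls <- function(status) {
  tibble::tibble(asv_id = names(status), status = unname(status),
                 sh_id = ifelse(status == "unknown", NA, "SH1"),
                 dist = ifelse(status == "unknown", NA_real_, 0.05),
                 kingdom = dplyr::case_when(
                   status == "known_fungi" ~ "Fungi",
                   status == "known_nonfungi" ~ "Metazoa",
                   TRUE ~ NA_character_),
                 phylum = NA_character_, class = NA_character_,
                 order = NA_character_, family = NA_character_,
                 genus = NA_character_, species = NA_character_)
}

test_that("pseudotaxa with a non-fungal majority are purged, ties kept", {
  h <- mk_hier(same_all_ranks(c("a", "b", "c"), "pseudophylum_0001"))
  calls <- mk_calls(c(a = "known_nonfungi", b = "known_nonfungi",
                      c = "known_fungi"))
  out <- purge_pseudotaxa(h, calls)
  expect_equal(nrow(out$hierarchy$membership), 0)
  expect_setequal(out$removed$asv_id, c("a", "b", "c"))

  # 1 vs 1 is not "more": retained
  h2 <- mk_hier(same_all_ranks(c("a", "b"), "pseudophylum_0001"))
  calls2 <- mk_calls(c(a = "known_nonfungi", b = "known_fungi"))
  out2 <- purge_pseudotaxa(h2, calls2)
  expect_equal(nrow(out2$removed), 0)
})

test_that("all-unknown removal applies at phylum rank only", {
  h <- mk_hier(same_all_ranks(c("a", "b"), "pseudophylum_0001"))
  calls <- mk_calls(c(a = "unknown", b = "unknown"))
  out <- purge_pseudotaxa(h, calls)
  expect_equal(nrow(out$hierarchy$membership), 0)

  # all-unknown genus pseudotaxon inside a known phylum is retained
  labs <- same_all_ranks(c("a", "b"), "pseudogenus_0001")
  labs$phylum <- c(a = "PhyKnown", b = "PhyKnown")
  labs$class <- c(a = "ClsKnown", b = "ClsKnown")
  labs$order <- c(a = "OrdKnown", b = "OrdKnown")
  labs$family <- c(a = "FamKnown", b = "FamKnown")
  h2 <- mk_hier(labs)
  out2 <- purge_pseudotaxa(h2, calls)
  expect_equal(nrow(out2$removed), 0)
})

test_that("every removed ASV lands in exactly one pseudophylum table", {
  b <- small_sim(seed = 29)
  res <- run_pipeline(b$data, b$sim$refs, out_dir = NULL)
  fun <- res$pseudophyla$fungi$ASV
  non <- res$pseudophyla$nonfungi$ASV
  expect_equal(length(intersect(fun, non)), 0)
  expect_setequal(non, res$removed$asv_id)
  retained <- res$hierarchy$membership$asv_id
  expect_true(all(fun %in% retained))
  expect_true(!any(non %in% retained))
})

test_that("pseudophylum summaries aggregate by majority best hit", {
  tab <- tibble::tibble(
    ASV = c("a", "b", "c", "d"),
    OTU = "OTU1",
    pseudophylum = "pseudophylum_0001",
    pseudospecies = c("ps1", "ps1", "ps2", "ps2"),
    sh_id = c("S1", "S2", "S3", NA),
    dist = c(0.05, 0.05, 0.02, NA),
    kingdom = "Fungi",
    phylum = c("PhylumX", "PhylumX", "Fungi_phy_unspecified", NA))
  # one extra ASV of PhylumX so majority counts 3
  tab <- dplyr::bind_rows(tab, dplyr::mutate(tab[1, ], ASV = "e"))
  s <- summarize_pseudophyla(tab, level = "phylum")
  expect_equal(s$majority_taxon, "PhylumX")
  expect_equal(s$n_asv, 5)
  expect_equal(s$n_majority, 3)
  expect_equal(s$n_unspecified, 1)
  expect_equal(s$n_nomatch, 1)
  expect_equal(s$mean_dist_majority, 0.05)
  expect_equal(s$mean_dist_unspecified, 0.02)
  expect_equal(s$n_psp, 2)
  # counts partition the total
  expect_equal(s$n_majority + s$n_minority + s$n_unspecified + s$n_nomatch,
               s$n_asv)
})

test_that("all-no-match pseudophyla group under 'no match'; ties go lexicographic", {
  tab <- tibble::tibble(
    ASV = c("a", "b"), OTU = NA_character_,
    pseudophylum = "pseudophylum_0002",
    pseudospecies = "ps1", sh_id = NA_character_, dist = NA_real_,
    kingdom = NA_character_, phylum = NA_character_)
  s <- summarize_pseudophyla(tab, level = "kingdom")
  expect_equal(s$majority_taxon, "no match")
  expect_equal(s$n_nomatch, 2)

  tie <- tibble::tibble(
    ASV = c("a", "b"), OTU = "O", pseudophylum = "pseudophylum_0003",
    pseudospecies = "ps1", sh_id = c("S1", "S2"), dist = c(0.1, 0.1),
    kingdom = "Fungi", phylum = c("PhylumB", "PhylumA"))
  s2 <- summarize_pseudophyla(tie, level = "phylum")
  expect_equal(s2$majority_taxon, "PhylumA")
})
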