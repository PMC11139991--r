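#' Classify ASVs by kingdom against annotated references
#'
#' Finds each ASV's best hit among kingdom-annotated reference sequences at
#' a global dissimilarity of at most `max_dissimilarity` (default 0.2, i.e.
#' similarity at least 0.8). ASVs whose best hit is annotated *Fungi* are
#' "known fungi"; a hit in another named kingdom makes them "known
#' non-fungi"; no hit, or a hit whose kingdom is unspecified, leaves the
#' kingdom unknown.
#'
#' @param asvs Tibble `asv_id`, `sequence`.
#' @param refs Reference tibble: first column ids (`sh_id`), `sequence`,
#'   and lineage columns `kingdom` ... `species` (possibly NA or
#'   "unspecified").
#' @param max_dissimilarity Hit threshold (default 0.2).
#' @param ... Passed to [nearest_reference()].
#' @return A tibble per ASV: `asv_id`, `status` (`known_fungi`,
#'   `known_nonfungi`, `unknown`), `sh_id`, `dist`, and the best match's
#'   lineage columns.
#' @export
classify_kingdom <- function(asvs, refs, max_dissimilarity = 0.2, ...) {
  assert_df_has(asvs, c("asv_id", "sequence"), "asvs")
  assert_df_has(refs, c("sequence", tax_ranks()), "refs")
  hits <- nearest_reference(asvs[, c("asv_id", "sequence")], refs,
                            max_dissimilarity = max_dissimilarity, ...)
  ref_lineage <- refs[, c(names(refs)[1], tax_ranks())]
  names(ref_lineage)[1] <- "ref_id"
  out <- dplyr::left_join(hits, ref_lineage, by = "ref_id")
  kingdom <- out$kingdom
  unspecified <- is.na(kingdom) | kingdom == "unspecified" |
    grepl("unspecified", kingdom)
  out$status <- dplyr::case_when(
    is.na(out$ref_id) ~ "unknown",
    unspecified ~ "unknown",
    kingdom == "Fungi" ~ "known_fungi",
    TRUE ~ "known_nonfungi"
  )
  names(out)[names(out) == "query_id"] <- "asv_id"
  names(out)[names(out) == "ref_id"] <- "sh_id"
  out[, c("asv_id", "status", "sh_id", "dist", tax_ranks())]
}

#' Purge non-fungal and unknowable pseudotaxa from a hierarchy
#'
#' Removes, with all their member ASVs, (a) pseudotaxa at any rank that
#' contain strictly more known non-fungal than known fungal ASVs, and (b)
#' phylum-rank pseudotaxa whose members are all of unknown kingdom.
#' Clusters labelled with known taxa are never flagged.
#'
#' @param hierarchy A `cluster_hierarchy` from [cluster_all_ranks()].
#' @param calls Kingdom calls from [classify_kingdom()] covering the ASVs of
#'   every pseudotaxon.
#' @return A list: `hierarchy` (retained), `removed` (tibble of removed
#'   membership rows joined with their kingdom calls).
#' @export
purge_pseudotaxa <- function(hierarchy, calls) {
  stopifnot(inherits(hierarchy, "cluster_hierarchy"))
  assert_df_has(calls, c("asv_id", "status"), "calls")
  mem <- hierarchy$membership
  status <- setNames(calls$status, calls$asv_id)
  drop_ids <- character(0)
  for (r in cluster_ranks()) {
    labs <- mem[[r]]
    for (l in unique(labs[is_pseudo(labs)])) {
      members <- mem$asv_id[labs == l]
      st <- status[members]
      if (any(is.na(st))) {
        stop("kingdom calls missing for pseudotaxon member(s): ",
             paste(head(members[is.na(st)], 5), collapse = ", "),
             call. = FALSE)
      }
      n_fun <- sum(st == "known_fungi")
      n_non <- sum(st == "known_nonfungi")
      if (n_non > n_fun ||
          (r == "phylum" && all(st == "unknown"))) {
        drop_ids <- c(drop_ids, members)
      }
    }
  }
  drop_ids <- unique(drop_ids)
  removed <- mem[mem$asv_id %in% drop_ids, , drop = FALSE] |>
    dplyr::left_join(calls, by = "asv_id")
  kept <- mem[!mem$asv_id %in% drop_ids, , drop = FALSE]
  out <- hierarchy
  out$membership <- kept
  out$otus <- hierarchy$otus[hierarchy$otus$otu_id %in% kept$otu_id, ,
                             drop = FALSE]
  list(hierarchy = out, removed = removed)
}

#' Build the fungal and non-fungal pseudophylum tables
#'
#' One row per ASV that could not be assigned to a known phylum: its
#' pseudophylum, its species-level cluster, and the closest reference match
#' with that match's lineage. ASVs of the retained hierarchy go to the
#' fungal table (with their OTU id); purged ASVs go to the non-fungal table
#' (no OTU id).
#'
#' @param hierarchy The retained `cluster_hierarchy`.
#' @param removed The `removed` tibble from [purge_pseudotaxa()].
#' @param calls Kingdom calls from [classify_kingdom()].
#' @return A list of two tibbles, `fungi` and `nonfungi`, with the
#'   `pseudophyla_fungi.csv` / `pseudophyla_nonfungi.csv` schemas.
#' @export
pseudophylum_tables <- function(hierarchy, removed, calls) {
  call_cols <- calls[, c("asv_id", "sh_id", "dist", tax_ranks())]
  mem <- hierarchy$membership
  fungi <- mem[is_pseudo(mem$phylum), , drop = FALSE] |>
    dplyr::left_join(call_cols, by = "asv_id") |>
    dplyr::transmute(ASV = .data$asv_id, OTU = .data$otu_id,
                     pseudophylum = .data$phylum.x,
                     pseudospecies = .data$species.x, sh_id = .data$sh_id,
                     dist = .data$dist, kingdom = .data$kingdom.y,
                     phylum = .data$phylum.y, class = .data$class.y,
                     order = .data$order.y, family = .data$family.y,
                     genus = .data$genus.y, species = .data$species.y)
  nonfungi <- removed |>
    dplyr::transmute(ASV = .data$asv_id, pseudophylum = .data$phylum.x,
                     pseudospecies = .data$species.x, sh_id = .data$sh_id,
                     dist = .data$dist, kingdom = .data$kingdom.y,
                     phylum = .data$phylum.y, class = .data$class.y,
                     order = .data$order.y, family = .data$family.y,
                     genus = .data$genus.y, species = .data$species.y)
  list(fungi = fungi, nonfungi = nonfungi)
}

#' Summarize pseudophyla by their majority best-hit taxon
#'
#' Groups pseudophyla by the most common best-hit taxon among their member
#' ASVs (the phylum of the best match for the fungal table, the kingdom for
#' the non-fungal table; ties broken by the lexicographically smaller
#' taxon). Reports, per majority taxon: the numbers of pseudophyla and
#' pseudospecies, ASV counts split into majority / minority (a different
#' named taxon) / unspecified (best hit unannotated at that level) /
#' no-match, and the corresponding mean best-hit distances. Pseudophyla
#' whose members all lack a match are grouped under `"no match"`.
#'
#' @param table A pseudophylum table (`fungi` or `nonfungi` element of
#'   [pseudophylum_tables()]).
#' @param level `"phylum"` or `"kingdom"`: the lineage level summarized.
#' @return A tibble with one row per majority taxon, ordered by total ASV
#'   count: `majority_taxon`, `n_pphy`, `n_psp`, `n_asv`, `n_majority`,
#'   `n_minority`, `n_unspecified`, `n_nomatch`, `mean_dist_majority`,
#'   `mean_dist_minority`, `mean_dist_unspecified`.
#' @export
summarize_pseudophyla <- function(table, level = c("phylum", "kingdom")) {
  level <- match.arg(level)
  assert_df_has(table, c("ASV", "pseudophylum", "pseudospecies", "dist",
                         level), "pseudophylum table")
  df <- tibble::tibble(
    asv = table$ASV,
    pphy = table$pseudophylum,
    psp = table$pseudospecies,
    dist = table$dist,
    taxon = table[[level]]
  )
  df$cat <- dplyr::case_when(
    is.na(df$dist) ~ "nomatch",
    is.na(df$taxon) | grepl("unspecified", df$taxon) ~ "unspecified",
    TRUE ~ "named"
  )
  # majority taxon per pseudophylum (unspecified is a candidate value;
  # all-no-match pseudophyla group under "no match")
  maj <- df |>
    dplyr::mutate(value = dplyr::case_when(
      .data$cat == "named" ~ .data$taxon,
      .data$cat == "unspecified" ~ "unspecified",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$pphy, .data$value) |>
    dplyr::arrange(.data$pphy, dplyr::desc(.data$n), .data$value) |>
    dplyr::slice_head(n = 1, by = "pphy")
  maj_of <- setNames(maj$value, maj$pphy)
  df$majority <- unname(maj_of[df$pphy])
  df$majority[is.na(df$majority)] <- "no match"
  df |>
    dplyr::summarise(
      n_pphy = dplyr::n_distinct(.data$pphy),
      n_psp = dplyr::n_distinct(.data$psp),
      n_asv = dplyr::n(),
      n_majority = sum(.data$cat == "named" & .data$taxon == .data$majority),
      n_minority = sum(.data$cat == "named" & .data$taxon != .data$majority),
      n_unspecified = sum(.data$cat == "unspecified"),
      n_nomatch = sum(.data$cat == "nomatch"),
      mean_dist_majority = mean(.data$dist[.data$cat == "named" &
                                             .data$taxon == .data$majority]),
      mean_dist_minority = mean(.data$dist[.data$cat == "named" &
                                             .data$taxon != .data$majority]),
      mean_dist_unspecified = mean(.data$dist[.data$cat == "unspecified"]),
      .by = "majority"
    ) |>
    dplyr::rename(majority_taxon = "majority") |>
    dplyr::arrange(dplyr::desc(.data$n_asv), .data$majority_taxon)
}
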