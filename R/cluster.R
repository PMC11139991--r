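#' Form cluster cores from confident taxonomic assignments
#'
#' At a given rank, ASVs assigned to a taxon with at least `confidence`
#' probability seed one cluster core per distinct taxon. Cores are never
#' merged by the later stages.
#'
#' @param assignments Long-format assignments: `asv_id`, `rank`, `taxon`,
#'   `prob`.
#' @param rank The rank at which to form cores.
#' @param confidence Minimum assignment probability (default 0.90).
#' @return A tibble `asv_id`, `taxon` with one row per confidently assigned
#'   ASV.
#' @export
form_cores <- function(assignments, rank, confidence = 0.90) {
  assert_df_has(assignments, c("asv_id", "rank", "taxon", "prob"),
                "assignments")
  assignments |>
    dplyr::filter(.data$rank == !!rank, !is.na(.data$taxon),
                  .data$prob >= confidence) |>
    dplyr::distinct(.data$asv_id, .keep_all = TRUE) |>
    dplyr::select("asv_id", "taxon")
}

#' Closed-reference assignment of unassigned ASVs to cluster cores
#'
#' Iteratively attaches unassigned ASVs to existing clusters: in each
#' iteration, every unassigned ASV within `threshold` of at least one
#' clustered ASV (core member or previously recruited member) joins the
#' cluster of its closest such member. Matches are computed against the
#' clustering state at the start of the iteration and applied
#' simultaneously; iteration continues to a fixed point. Cores are never
#' merged: an ASV within the threshold of two clusters joins only the
#' closest one (ties: larger cluster, then lexicographically smaller label).
#'
#' @param clusters Tibble `asv_id`, `label` of current cluster members.
#' @param unassigned Character vector of unassigned ASV ids.
#' @param distmx A `sparse_dist` tibble.
#' @param threshold Join threshold.
#' @return A list: `clusters` (tibble `asv_id`, `label`, `recruited`
#'   logical) and `unassigned` (ids that remained unattached).
#' @export
closed_reference_assign <- function(clusters, unassigned, distmx, threshold) {
  assert_df_has(clusters, c("asv_id", "label"), "clusters")
  members <- dplyr::mutate(clusters, recruited = FALSE)
  pool <- unassigned
  ids <- c(members$asv_id, pool)
  e <- distmx[distmx$dist <= threshold & distmx$id1 %in% ids &
                distmx$id2 %in% ids, , drop = FALSE]
  # symmetric edge list for neighbour lookup
  e2 <- tibble::tibble(a = c(e$id1, e$id2), b = c(e$id2, e$id1),
                       d = c(e$dist, e$dist))
  repeat {
    if (length(pool) == 0 || nrow(members) == 0) break
    lab_of <- setNames(members$label, members$asv_id)
    size_of <- table(members$label)
    cand <- e2[e2$a %in% pool & e2$b %in% members$asv_id, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand$label <- unname(lab_of[cand$b])
    cand$size <- as.integer(size_of[cand$label])
    joins <- cand |>
      dplyr::arrange(.data$a, .data$d, dplyr::desc(.data$size),
                     .data$label) |>
      dplyr::slice_head(n = 1, by = "a")
    members <- dplyr::bind_rows(
      members,
      tibble::tibble(asv_id = joins$a, label = joins$label, recruited = TRUE))
    pool <- setdiff(pool, joins$a)
  }
  list(clusters = members, unassigned = pool)
}

#' De novo single-linkage clustering into pseudotaxa
#'
#' Clusters the remaining unattached ASVs at a rank as the connected
#' components of the graph with edges at dissimilarity `<= threshold`. Each
#' component becomes a pseudotaxon named `pseudo{rank}_{NNNN}` with
#' zero-padded sequential numbering continuing from `counter`; components
#' are numbered in order of their smallest member id.
#'
#' @param remaining Character vector of ASV ids to cluster.
#' @param distmx A `sparse_dist` tibble.
#' @param threshold Join threshold.
#' @param rank Rank of the clusters (used in the placeholder name).
#' @param counter Last used pseudotaxon number at this rank (default 0).
#' @return A list: `clusters` (tibble `asv_id`, `label`) and `counter` (the
#'   updated number).
#' @export
denovo_cluster <- function(remaining, distmx, threshold, rank, counter = 0L) {
  if (length(remaining) == 0) {
    return(list(clusters = tibble::tibble(asv_id = character(0),
                                          label = character(0)),
                counter = counter))
  }
  remaining <- sort(remaining)
  comp <- single_linkage(remaining, distmx, threshold)
  # components ordered by smallest member id (ids are sorted, so first
  # occurrence order is that order)
  ord <- match(comp, unique(comp))
  labels <- pseudo_name(rank, counter + ord)
  list(clusters = tibble::tibble(asv_id = remaining, label = labels),
       counter = counter + max(ord))
}

#' Three-stage rank-nested constrained clustering of ASVs
#'
#' The pipeline's core algorithm. For each taxonomic rank from phylum to
#' species, and within each cluster of the rank above: (1) cluster cores are
#' formed by ASVs confidently assigned to taxa at that rank
#' ([form_cores()]); (2) unassigned ASVs are attached to the closest cluster
#' by iterated closed-reference matching ([closed_reference_assign()]);
#' (3) still-unclustered ASVs are grouped de novo into pseudotaxa
#' ([denovo_cluster()]). Thresholds are resolved per enclosing supertaxon
#' via [lookup_threshold()]. The species-level clusters are the final OTUs;
#' each OTU is labelled by its full 7-rank lineage (known taxa and/or
#' placeholders) and represented by its most abundant member ASV.
#'
#' @param asvs Tibble `asv_id`, `sequence`, `reads`.
#' @param assignments Long-format assignments (`asv_id`, `rank`, `taxon`,
#'   `prob`).
#' @param distmx A `sparse_dist` over the ASVs.
#' @param thresholds A `threshold_tbl` containing at least the root entries.
#' @param confidence Assignment probability threshold (default 0.90).
#' @return A `cluster_hierarchy` object: a list with `membership` (tibble of
#'   per-ASV labels and stage provenance at every rank, plus `otu_id`),
#'   `otus` (tibble `otu_id`, lineage, representative `sequence`), and
#'   `counters` (pseudotaxon counters per rank).
#' @export
cluster_all_ranks <- function(asvs, assignments, distmx, thresholds,
                              confidence = 0.90) {
  assert_df_has(asvs, c("asv_id", "sequence", "reads"), "asvs")
  if (anyDuplicated(asvs$asv_id) > 0) {
    stop("duplicate asv_id in asvs", call. = FALSE)
  }
  stray <- setdiff(assignments$asv_id, asvs$asv_id)
  if (length(stray) > 0) {
    stop("assignments refer to unknown ASV(s): ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  stray_d <- setdiff(c(distmx$id1, distmx$id2), asvs$asv_id)
  if (length(stray_d) > 0) {
    stop("distance matrix refers to unknown ASV(s): ",
         paste(head(stray_d, 5), collapse = ", "), call. = FALSE)
  }

  ids <- sort(asvs$asv_id)
  membership <- tibble::tibble(asv_id = ids, kingdom = "Fungi")
  # parent_key identifies a cluster by its full label path (labels of known
  # taxa are not guaranteed unique across parents a priori)
  parent_key <- setNames(rep("Fungi", length(ids)), ids)
  counters <- setNames(rep(0L, 6), cluster_ranks())
  lineage_of_key <- list(Fungi = c(kingdom = "Fungi"))

  for (r in cluster_ranks()) {
    cores_all <- form_cores(assignments, r, confidence)
    label_col <- setNames(rep(NA_character_, length(ids)), ids)
    prov_col <- setNames(rep(NA_character_, length(ids)), ids)
    new_key <- parent_key
    for (pk in sort(unique(parent_key))) {
      members <- ids[parent_key == pk]
      lineage <- lineage_of_key[[pk]]
      t_r <- lookup_threshold(lineage, r, thresholds)
      cores <- cores_all[cores_all$asv_id %in% members, , drop = FALSE]
      core_clusters <- tibble::tibble(asv_id = cores$asv_id,
                                      label = cores$taxon)
      pool <- setdiff(members, cores$asv_id)
      cr <- closed_reference_assign(core_clusters, pool, distmx, t_r)
      dn <- denovo_cluster(cr$unassigned, distmx, t_r, r,
                           counter = counters[[r]])
      counters[[r]] <- dn$counter
      lab <- c(setNames(cr$clusters$label, cr$clusters$asv_id),
               setNames(dn$clusters$label, dn$clusters$asv_id))
      prv <- c(setNames(ifelse(cr$clusters$recruited, "closed_ref", "core"),
                        cr$clusters$asv_id),
               setNames(rep("denovo", nrow(dn$clusters)),
                        dn$clusters$asv_id))
      label_col[members] <- lab[members]
      prov_col[members] <- prv[members]
      for (l in unique(lab)) {
        key <- paste(pk, l, sep = "|")
        lineage_of_key[[key]] <- c(lineage, setNames(l, r))
      }
      new_key[members] <- paste(pk, lab[members], sep = "|")
    }
    membership[[r]] <- unname(label_col[membership$asv_id])
    membership[[paste0("prov_", r)]] <- unname(prov_col[membership$asv_id])
    parent_key <- new_key
  }

  # species-level clusters are the OTUs
  reads_of <- setNames(asvs$reads, asvs$asv_id)
  seq_of <- setNames(asvs$sequence, asvs$asv_id)
  keys <- sort(unique(parent_key))
  otu_ids <- setNames(sprintf("OTU_%05d", seq_along(keys)), keys)
  membership$otu_id <- unname(otu_ids[parent_key[membership$asv_id]])
  otus <- purrr::map_dfr(keys, function(k) {
    lin <- lineage_of_key[[k]]
    mem <- names(parent_key)[parent_key == k]
    rep_asv <- mem[order(-reads_of[mem], mem)][1]
    tibble::as_tibble(c(list(otu_id = unname(otu_ids[[k]])),
                        as.list(lin),
                        list(rep_asv = rep_asv,
                             sequence = unname(seq_of[rep_asv]))))
  })
  structure(list(membership = membership, otus = otus, counters = counters),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat("<cluster_hierarchy>\n")
  cat("  ", nrow(x$membership), "ASVs in", nrow(x$otus),
      "species-level OTUs\n")
  for (r in cluster_ranks()) {
    labs <- unique(x$membership[[r]])
    cat(sprintf("  %-8s %4d clusters (%d pseudotaxa)\n", r, length(labs),
                sum(is_pseudo(labs))))
  }
  invisible(x)
}

#' Tidy a cluster hierarchy into a per-ASV tibble
#'
#' @param x A `cluster_hierarchy`.
#' @param ... Unused.
#' @return A tibble with one row per ASV: labels at every rank, per-rank
#'   stage provenance and the final `otu_id`.
#' @export
tidy.cluster_hierarchy <- function(x, ...) {
  x$membership
}

#' One-row summary of a cluster hierarchy
#'
#' @param x A `cluster_hierarchy`.
#' @param ... Unused.
#' @return A tibble with ASV/OTU counts and the number of pseudotaxa per
#'   rank.
#' @export
glance.cluster_hierarchy <- function(x, ...) {
  out <- tibble::tibble(n_asvs = nrow(x$membership), n_otus = nrow(x$otus))
  for (r in cluster_ranks()) {
    labs <- unique(x$membership[[r]])
    out[[paste0("n_", r)]] <- length(labs)
    out[[paste0("n_pseudo_", r)]] <- sum(is_pseudo(labs))
  }
  out
}
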