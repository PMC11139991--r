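#' Pairwise global-alignment dissimilarity
#'
#' Computes, for each pair `a[i]`, `b[i]`, the dissimilarity
#' `(mismatches + gap_penalty * internal gap columns) / alignment columns`
#' under an optimal global alignment, where terminal-gap columns are excluded
#' from both numerator and denominator. Sequences identical except for end
#' gaps therefore have dissimilarity 0, and fully mismatched sequences have
#' dissimilarity 1 (Table-5 semantics: 0.0 = all bases identical, 1.0 = all
#' bases different).
#'
#' @param a,b Character vectors of equal length (DNA sequences).
#' @param gap_penalty Cost of one internal gap column (default 1).
#' @return Numeric vector of dissimilarities in `[0, 1]`.
#' @export
pairwise_dissimilarity <- function(a, b, gap_penalty = 1) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) return(numeric(0))
  seqs <- c(toupper(a), toupper(b))
  n <- length(a)
  pair_dissim_cpp(seqs, seq_len(n), n + seq_len(n), gap_penalty)
}

# calibrated k-mer distance cutoff -> raw (1 - shared word fraction) cutoff.
# Shared 8-mer fraction between sequences at alignment divergence d decays
# roughly like (1 - d)^k, so the cutoff is applied on the 1 - F^(1/k) scale.
raw_kmer_cutoff <- function(cutoff, k) 1 - (1 - cutoff)^k

#' Sparse pairwise dissimilarity matrix
#'
#' Computes global-alignment dissimilarities (see
#' [pairwise_dissimilarity()]) for all sequence pairs passing a k-mer
#' prefilter, and keeps pairs with dissimilarity at most `max_dist`. Absent
#' pairs mean "farther than `max_dist`".
#'
#' The k-mer prefilter (word length `kmer_k`) is an admissible speedup only:
#' the cutoff is interpreted on the calibrated word-match scale
#' `1 - F^(1/k)` (with `F` the shared-word fraction), which approximates the
#' alignment divergence, so that near pairs are never skipped. Set
#' `use_prefilter = FALSE` to force all pairs to be aligned.
#'
#' @param seqs A data frame whose first column holds unique sequence ids and
#'   which has a `sequence` column.
#' @param max_dist Maximum stored dissimilarity (default 0.6).
#' @param kmer_prefilter Prefilter cutoff on the calibrated k-mer distance
#'   (default 0.4).
#' @param gap_penalty Internal gap-column penalty (default 1).
#' @param kmer_k Word length of the prefilter (default 8).
#' @param use_prefilter Disable to align every pair.
#' @return A `sparse_dist` tibble with columns `id1`, `id2`, `dist`
#'   (`id1 < id2` lexicographically) and attribute `max_dist`.
#' @export
sparse_distances <- function(seqs, max_dist = 0.6, kmer_prefilter = 0.4,
                             gap_penalty = 1, kmer_k = 8L,
                             use_prefilter = TRUE) {
  assert_df_has(seqs, "sequence", "seqs")
  ids <- as.character(seqs[[1]])
  ss <- toupper(seqs$sequence)
  if (length(ids) < 1) stop("no sequences supplied", call. = FALSE)
  if (anyDuplicated(ids) > 0) stop("duplicate sequence ids", call. = FALSE)
  n <- length(ids)
  if (n == 1) {
    return(new_sparse_dist(tibble::tibble(id1 = character(0),
                                          id2 = character(0),
                                          dist = numeric(0)), max_dist))
  }
  if (use_prefilter) {
    pairs <- kmer_candidate_pairs_cpp(ss, as.integer(kmer_k),
                                      raw_kmer_cutoff(kmer_prefilter, kmer_k))
    i <- pairs[, 1]; j <- pairs[, 2]
  } else {
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  }
  if (length(i) == 0) {
    return(new_sparse_dist(tibble::tibble(id1 = character(0),
                                          id2 = character(0),
                                          dist = numeric(0)), max_dist))
  }
  d <- pair_dissim_cpp(ss, i, j, gap_penalty)
  keep <- d <= max_dist
  out <- tibble::tibble(id1 = ids[i[keep]], id2 = ids[j[keep]],
                        dist = d[keep])
  swap <- out$id1 > out$id2
  tmp <- out$id1[swap]; out$id1[swap] <- out$id2[swap]; out$id2[swap] <- tmp
  out <- dplyr::arrange(out, .data$id1, .data$id2)
  new_sparse_dist(out, max_dist)
}

new_sparse_dist <- function(df, max_dist) {
  attr(df, "max_dist") <- max_dist
  class(df) <- c("sparse_dist", class(df))
  df
}

#' Write / read a sparse distance matrix as CSV
#'
#' Three-column CSV (`id1`, `id2`, `dist`) with ids in lexicographic pair
#' order.
#'
#' @param distmx A `sparse_dist` tibble.
#' @param path File path.
#' @param max_dist Cutoff to attach when reading.
#' @return `path` (write) or a `sparse_dist` tibble (read).
#' @export
write_distmx <- function(distmx, path) {
  readr::write_csv(distmx[, c("id1", "id2", "dist")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distmx
#' @export
read_distmx <- function(path, max_dist = 0.6) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_df_has(df, c("id1", "id2", "dist"), "distance matrix")
  new_sparse_dist(df, max_dist)
}

# restrict a sparse_dist to a set of ids
subset_dist <- function(distmx, ids) {
  distmx[distmx$id1 %in% ids & distmx$id2 %in% ids, , drop = FALSE]
}

#' Collapse ASVs identical except for end gaps
#'
#' Merges ASVs whose optimal global alignment differs only at terminal gap
#' positions (alignment dissimilarity exactly 0). Merging is transitive:
#' merge classes are the connected components of the end-gap-identity
#' relation. The most abundant member (ties broken by lexicographically
#' smallest id) becomes the representative, and read counts are summed.
#'
#' @param asvs A data frame with columns `asv_id`, `sequence` and, unless
#'   `counts` is given, `reads` (total reads per ASV).
#' @param counts Optional long-format counts (`sample_id`, `asv_id`,
#'   `reads`) used to derive per-ASV totals.
#' @param gap_penalty Internal gap-column penalty (default 1).
#' @return A list with `asvs` (merged tibble `asv_id`, `sequence`, `reads`)
#'   and `map` (tibble `asv_id`, `representative`).
#' @export
collapse_end_gap_duplicates <- function(asvs, counts = NULL, gap_penalty = 1) {
  assert_df_has(asvs, c("asv_id", "sequence"), "asvs")
  if (any(nchar(asvs$sequence) == 0)) {
    stop("empty sequence(s) in input", call. = FALSE)
  }
  if (is.null(counts)) {
    assert_df_has(asvs, "reads", "asvs")
    totals <- setNames(as.numeric(asvs$reads), asvs$asv_id)
  } else {
    assert_df_has(counts, c("asv_id", "reads"), "counts")
    tot <- dplyr::summarise(counts, reads = sum(.data$reads),
                            .by = "asv_id")
    totals <- setNames(as.numeric(tot$reads), tot$asv_id)
    totals <- setNames(ifelse(is.na(totals[asvs$asv_id]), 0,
                              totals[asvs$asv_id]), asvs$asv_id)
  }
  n <- nrow(asvs)
  ids <- asvs$asv_id
  comp <- seq_len(n)
  if (n > 1) {
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
    d <- pair_dissim_cpp(toupper(asvs$sequence), i, j, gap_penalty)
    zero <- d == 0
    if (any(zero)) {
      g <- igraph::graph_from_edgelist(cbind(ids[i[zero]], ids[j[zero]]),
                                       directed = FALSE)
      g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
      comp <- igraph::components(g)$membership[ids]
    }
  }
  df <- tibble::tibble(asv_id = ids, sequence = toupper(asvs$sequence),
                       reads = unname(totals[ids]), comp = comp)
  merged <- df |>
    dplyr::arrange(.data$comp, dplyr::desc(.data$reads), .data$asv_id) |>
    dplyr::mutate(representative = .data$asv_id[1], .by = "comp")
  map <- merged[, c("asv_id", "representative")] |>
    dplyr::arrange(.data$asv_id)
  out <- merged |>
    dplyr::summarise(asv_id = .data$representative[1],
                     sequence = .data$sequence[1],
                     reads = sum(.data$reads), .by = "comp") |>
    dplyr::select(!"comp") |>
    dplyr::arrange(.data$asv_id)
  list(asvs = out, map = map)
}

#' Nearest reference search
#'
#' For each query sequence, finds the minimum-dissimilarity reference within
#' `max_dissimilarity`; ties are broken by the lexicographically smallest
#' reference id. Queries with no reference within the threshold get `NA`.
#'
#' @param queries A data frame (first column ids, plus `sequence`) or a
#'   character vector of sequences.
#' @param refs A data frame (first column ids, plus `sequence`).
#' @param max_dissimilarity Maximum dissimilarity of a reported hit.
#' @param gap_penalty Internal gap-column penalty (default 1).
#' @param use_prefilter Skip obviously distant query/reference pairs with a
#'   calibrated k-mer screen (margin 0.15 above `max_dissimilarity`).
#' @return A tibble with one row per query: `query_id`, `ref_id`, `dist`
#'   (`ref_id`/`dist` are `NA` when there is no hit).
#' @export
nearest_reference <- function(queries, refs, max_dissimilarity,
                              gap_penalty = 1, use_prefilter = TRUE) {
  if (is.character(queries)) {
    queries <- tibble::tibble(query_id = names(queries) %||%
                                as.character(seq_along(queries)),
                              sequence = queries)
  }
  assert_df_has(queries, "sequence", "queries")
  assert_df_has(refs, "sequence", "refs")
  if (nrow(refs) == 0) stop("reference set is empty", call. = FALSE)
  qid <- as.character(queries[[1]])
  rid <- as.character(refs[[1]])
  qs <- toupper(queries$sequence)
  rs <- toupper(refs$sequence)
  nq <- length(qs); nr <- length(rs)
  empty <- tibble::tibble(query_id = qid, ref_id = NA_character_,
                          dist = NA_real_)
  if (nq == 0) return(empty)
  seqs <- c(qs, rs)
  if (use_prefilter) {
    cut <- min(max_dissimilarity + 0.15, 0.95)
    pairs <- kmer_candidate_pairs_cpp(seqs, 8L, raw_kmer_cutoff(cut, 8L))
    keep <- pairs[, 1] <= nq & pairs[, 2] > nq
    i <- pairs[keep, 1]; j <- pairs[keep, 2]
  } else {
    i <- rep(seq_len(nq), each = nr)
    j <- rep(nq + seq_len(nr), times = nq)
  }
  if (length(i) == 0) return(empty)
  d <- pair_dissim_cpp(seqs, i, j, gap_penalty)
  hits <- tibble::tibble(query_id = qid[i], ref_id = rid[j - nq], dist = d) |>
    dplyr::filter(.data$dist <= max_dissimilarity) |>
    dplyr::arrange(.data$query_id, .data$dist, .data$ref_id) |>
    dplyr::slice_head(n = 1, by = "query_id")
  dplyr::left_join(tibble::tibble(query_id = qid), hits, by = "query_id")
}
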