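#' Multi-class F-measure of a clustering against reference labels
#'
#' Class-size-weighted mean, over reference classes, of the best harmonic
#' mean of precision and recall attained against any cluster:
#' `F = sum_c (n_c / N) * max_k 2 P(c,k) R(c,k) / (P(c,k) + R(c,k))` with
#' `P(c,k) = |c & k| / |k|` and `R(c,k) = |c & k| / n_c`. Equals 1 exactly
#' when the partition coincides with the label classes.
#'
#' @param clusters Vector of cluster memberships (one element per sequence).
#' @param labels Vector of reference labels, aligned with `clusters`.
#' @return The F-measure, a number in `[0, 1]`.
#' @export
fmeasure <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  if (length(clusters) == 0) stop("empty input", call. = FALSE)
  m <- table(labels, clusters)
  n_c <- rowSums(m)
  n_k <- colSums(m)
  p <- sweep(m, 2, n_k, "/")
  r <- sweep(m, 1, n_c, "/")
  f <- 2 * p * r / (p + r)
  f[m == 0] <- 0
  sum(n_c / sum(n_c) * apply(f, 1, max))
}

#' Single-linkage clustering at a fixed threshold
#'
#' Connected components of the graph joining pairs with dissimilarity
#' `<= threshold`; pairs absent from the sparse matrix are treated as
#' farther than the threshold.
#'
#' @param ids Character vector of sequence ids.
#' @param distmx A `sparse_dist` tibble (see [sparse_distances()]).
#' @param threshold Join threshold (closed: join iff `d <= t`).
#' @return Integer vector of component memberships, named by `ids`.
#' @export
single_linkage <- function(ids, distmx, threshold) {
  e <- distmx[distmx$dist <= threshold &
                distmx$id1 %in% ids & distmx$id2 %in% ids, , drop = FALSE]
  comp <- dsu_components(ids, e$id1, e$id2)
  setNames(comp, ids)
}

# union-find components over the given edge list
dsu_components <- function(ids, from, to) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  fi <- match(from, ids)
  ti <- match(to, ids)
  for (k in seq_along(fi)) {
    a <- find(fi[k]); b <- find(ti[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Optimize a single-linkage clustering threshold by F-measure
#'
#' Evaluates the multi-class F-measure of single-linkage clustering at every
#' grid threshold `t` in `{0, grid_step, ..., max_dist}` and returns the
#' smallest `t` attaining the maximal F. A supertaxon/subrank combination is
#' eligible only when it has at least `min_subtaxa` distinct subtaxa
#' represented by at least `min_refs` reference sequences in total.
#'
#' @param ids Character vector of reference sequence ids.
#' @param labels Subtaxon label per reference, aligned with `ids`.
#' @param distmx A `sparse_dist` tibble over (at least) these ids.
#' @param grid_step Threshold grid resolution (default 0.001).
#' @param max_dist Upper end of the grid; defaults to the matrix cutoff.
#' @param min_subtaxa,min_refs Eligibility minima (defaults 5 and 10).
#' @return A one-row tibble: `threshold`, `fscore`, `n_subtaxa`, `n_refs`,
#'   `eligible`. When ineligible, `threshold` and `fscore` are `NA`.
#' @export
optimize_threshold <- function(ids, labels, distmx, grid_step = 0.001,
                               max_dist = attr(distmx, "max_dist") %||% 0.6,
                               min_subtaxa = 5L, min_refs = 10L) {
  stopifnot(length(ids) == length(labels))
  keep <- !is.na(labels)
  ids <- ids[keep]; labels <- as.character(labels[keep])
  n_refs <- length(ids)
  n_subtaxa <- dplyr::n_distinct(labels)
  if (n_subtaxa < min_subtaxa || n_refs < min_refs) {
    return(tibble::tibble(threshold = NA_real_, fscore = NA_real_,
                          n_subtaxa = n_subtaxa, n_refs = n_refs,
                          eligible = FALSE))
  }
  e <- distmx[distmx$id1 %in% ids & distmx$id2 %in% ids, , drop = FALSE]
  e <- e[order(e$dist), , drop = FALSE]
  grid <- seq(0, max_dist, by = grid_step)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  fi <- match(e$id1, ids); ti <- match(e$id2, ids)
  next_edge <- 1L
  best_f <- -Inf; best_t <- NA_real_
  f_cur <- NA_real_
  for (t in grid) {
    changed <- FALSE
    while (next_edge <= nrow(e) && e$dist[next_edge] <= t) {
      a <- find(fi[next_edge]); b <- find(ti[next_edge])
      if (a != b) { parent[max(a, b)] <- min(a, b); changed <- TRUE }
      next_edge <- next_edge + 1L
    }
    if (changed || is.na(f_cur)) {
      roots <- vapply(seq_len(n), find, integer(1))
      f_cur <- fmeasure(roots, labels)
    }
    if (f_cur > best_f + 1e-12) { best_f <- f_cur; best_t <- t }
  }
  tibble::tibble(threshold = best_t, fscore = best_f, n_subtaxa = n_subtaxa,
                 n_refs = n_refs, eligible = TRUE)
}

#' Build the per-(supertaxon, subrank) threshold table
#'
#' Optimizes thresholds for clustering all Fungi into each rank from phylum
#' to species; each phylum into ranks class to species; and so on down to
#' each genus into species. Ineligible combinations (fewer than five subtaxa
#' or ten references) get no entry and are served by the fallback chain of
#' [lookup_threshold()].
#'
#' @param refs Reference tibble: first column ids, plus lineage columns
#'   `kingdom` ... `species` (NA where unannotated).
#' @param distmx A `sparse_dist` over the reference ids.
#' @param grid_step,max_dist,min_subtaxa,min_refs See [optimize_threshold()].
#' @return A `threshold_tbl` tibble: `supertaxon`, `superrank`, `subrank`,
#'   `threshold`, `fscore`, `n_subtaxa`, `n_refs`.
#' @export
build_threshold_table <- function(refs, distmx, grid_step = 0.001,
                                  max_dist = attr(distmx, "max_dist") %||% 0.6,
                                  min_subtaxa = 5L, min_refs = 10L) {
  assert_df_has(refs, tax_ranks(), "refs")
  ids <- as.character(refs[[1]])
  rows <- list()
  # root = all Fungi (non-fungal references play no part in threshold
  # optimization)
  supersets <- list(list(supertaxon = "Fungi", superrank = "kingdom",
                         member = !is.na(refs$kingdom) &
                           refs$kingdom == "Fungi"))
  for (r in tax_ranks()[2:6]) {
    for (taxon in sort(unique(stats::na.omit(refs[[r]])))) {
      supersets[[length(supersets) + 1]] <-
        list(supertaxon = taxon, superrank = r,
             member = !is.na(refs[[r]]) & refs[[r]] == taxon)
    }
  }
  for (s in supersets) {
    sub_ranks <- tax_ranks()[(rank_index(s$superrank) + 1):7]
    for (sr in sub_ranks) {
      lab <- refs[[sr]][s$member]
      opt <- optimize_threshold(ids[s$member], lab, distmx,
                                grid_step = grid_step, max_dist = max_dist,
                                min_subtaxa = min_subtaxa,
                                min_refs = min_refs)
      if (opt$eligible) {
        rows[[length(rows) + 1]] <-
          dplyr::bind_cols(tibble::tibble(supertaxon = s$supertaxon,
                                          superrank = s$superrank,
                                          subrank = sr),
                           opt[, c("threshold", "fscore", "n_subtaxa",
                                   "n_refs")])
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(supertaxon = character(0), superrank = character(0),
                   subrank = character(0), threshold = numeric(0),
                   fscore = numeric(0), n_subtaxa = integer(0),
                   n_refs = integer(0))
  class(out) <- c("threshold_tbl", class(out))
  out
}

#' Resolve a clustering threshold through the fallback chain
#'
#' Returns the optimized threshold of the most specific ancestor taxon in
#' `lineage` that has a table entry for `subrank`, walking ancestor by
#' ancestor up to the root (all Fungi). Pseudotaxon labels and missing
#' lineage levels are skipped.
#'
#' @param lineage Named character vector of taxon names (names in
#'   `tax_ranks()`), or an unnamed vector ordered kingdom downwards.
#' @param subrank The rank being clustered.
#' @param table A `threshold_tbl` from [build_threshold_table()].
#' @return The threshold (a single number).
#' @export
lookup_threshold <- function(lineage, subrank, table) {
  if (is.null(names(lineage))) {
    names(lineage) <- tax_ranks()[seq_along(lineage)]
  }
  anc_ranks <- rev(tax_ranks()[seq_len(rank_index(subrank) - 1)])
  for (r in anc_ranks) {
    taxon <- if (r == "kingdom") "Fungi"
             else if (r %in% names(lineage)) lineage[[r]]
             else NA_character_
    if (is.na(taxon) || (r != "kingdom" && is_pseudo(taxon))) next
    hit <- table$threshold[table$supertaxon == taxon &
                             table$subrank == subrank]
    if (length(hit) > 0) return(hit[1])
  }
  stop("no threshold entry found for subrank '", subrank,
       "' anywhere in the lineage (root entry missing)", call. = FALSE)
}

#' Write / read a threshold table as CSV
#'
#' @param table A `threshold_tbl`.
#' @param path File path.
#' @return `path` (write) or a `threshold_tbl` (read).
#' @export
write_threshold_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_df_has(df, c("supertaxon", "superrank", "subrank", "threshold",
                      "fscore", "n_subtaxa", "n_refs"), "threshold table")
  class(df) <- c("threshold_tbl", class(df))
  df
}
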