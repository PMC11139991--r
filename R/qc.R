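#' Filter samples by sequencing depth
#'
#' Depth counts all reads of the sample (fungal and spike alike). Samples
#' are kept when depth is at least `threshold` (default 10,000 reads).
#'
#' @param counts Long-format counts: `sample_id`, `asv_id`, `reads`.
#' @param threshold Minimum total reads (default 10000).
#' @return A `depth_report` tibble: `sample_id`, `depth`, `kept`. Use
#'   [glance.depth_report()] for the discard summary.
#' @export
filter_by_depth <- function(counts, threshold = 10000L) {
  assert_df_has(counts, c("sample_id", "reads"), "counts")
  if (any(counts$reads < 0)) stop("negative read counts", call. = FALSE)
  out <- counts |>
    dplyr::summarise(depth = sum(.data$reads), .by = "sample_id") |>
    dplyr::mutate(kept = .data$depth >= threshold) |>
    dplyr::arrange(.data$sample_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("depth_report", class(out))
  out
}

#' Summary of a depth report
#'
#' @param x A `depth_report` from [filter_by_depth()].
#' @param ... Unused.
#' @return A tibble: `n_samples`, `n_discarded`, `percent_discarded`
#'   (one decimal; NA for an empty table) and the threshold used.
#' @export
glance.depth_report <- function(x, ...) {
  n <- nrow(x)
  nd <- sum(!x$kept)
  tibble::tibble(n_samples = n, n_discarded = nd,
                 percent_discarded = if (n > 0) round(100 * nd / n, 1)
                                     else NA_real_,
                 threshold = attr(x, "threshold"))
}

#' Expected richness under rarefaction
#'
#' Analytic expectation of the number of OTUs observed when subsampling
#' `depth` reads without replacement from one sample:
#' `S(m) = sum_k [1 - choose(N - N_k, m) / choose(N, m)]` for per-OTU
#' counts `N_k` summing to `N` (the hypergeometric rarefaction formula,
#' computed by `vegan::rarefy`).
#'
#' @param counts Numeric vector of per-OTU read counts in one sample.
#' @param depth Subsample size; must not exceed `sum(counts)`.
#' @return The expected OTU count (a single number).
#' @export
rarefied_richness <- function(counts, depth) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (depth > total) {
    stop("depth (", depth, ") exceeds total reads (", total, ")",
         call. = FALSE)
  }
  if (depth == 0) return(0)
  # vegan warns whenever the count vector has no singletons; the expectation
  # formula is exact regardless, so the warning is noise here
  withCallingHandlers(
    as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depth)),
    warning = function(w) {
      if (grepl("observed count data", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Rarefaction curves for a set of samples
#'
#' Expected richness at a ladder of depths for every sample. Depths above a
#' sample's total reads are dropped for that sample. Whether spike reads
#' count towards depth is decided by what the supplied count table
#' contains; pass fungal-only counts for fungal rarefaction.
#'
#' @param counts Long-format counts: `sample_id`, `asv_id`, `reads`.
#' @param depths Integer vector of rarefaction depths.
#' @return A tibble: `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  assert_df_has(counts, c("sample_id", "asv_id", "reads"), "counts")
  by_sample <- split(counts$reads, counts$sample_id)
  purrr::imap_dfr(by_sample, function(v, sid) {
    v <- v[v > 0]
    ok <- depths <= sum(v)
    tibble::tibble(sample_id = sid, depth = depths[ok],
                   richness = vapply(depths[ok],
                                     function(m) rarefied_richness(v, m),
                                     numeric(1)))
  })
}

#' Negative-control contamination report
#'
#' For each negative control, counts its fungal reads (spike-flagged ASVs
#' excluded) and, when reads are present, flags the co-run study sample
#' with the highest total abundance over the units shared with the control
#' as the candidate cross-contamination source.
#'
#' @param counts Long-format counts (`sample_id`, `asv_id`, `reads`);
#'   `asv_id` may equally hold OTU ids.
#' @param controls Character vector of negative-control sample ids.
#' @param runs Optional tibble `sample_id`, `seqrun`; candidate sources are
#'   restricted to samples of the control's run. Without it, all non-control
#'   samples are candidates.
#' @param spikes Optional tibble `asv_id`, `spike` (logical); spike units
#'   are excluded from fungal read counts.
#' @return A `negctrl_report` tibble: `sample_id`, `fungal_reads`,
#'   `n_units`, `candidate_source`, `source_shared_reads`. Summary via
#'   [glance.negctrl_report()].
#' @export
negative_control_report <- function(counts, controls, runs = NULL,
                                    spikes = NULL) {
  assert_df_has(counts, c("sample_id", "asv_id", "reads"), "counts")
  unknown <- setdiff(controls, unique(counts$sample_id))
  if (length(unknown) > 0) {
    stop("unknown control id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fungal <- counts
  if (!is.null(spikes)) {
    spike_ids <- spikes$asv_id[spikes$spike]
    fungal <- fungal[!fungal$asv_id %in% spike_ids, , drop = FALSE]
  }
  fungal <- fungal[fungal$reads > 0, , drop = FALSE]
  run_of <- NULL
  if (!is.null(runs)) run_of <- setNames(runs$seqrun, runs$sample_id)
  rows <- purrr::map_dfr(sort(controls), function(cid) {
    cc <- fungal[fungal$sample_id == cid, , drop = FALSE]
    total <- sum(cc$reads)
    cand_id <- NA_character_
    cand_reads <- NA_real_
    if (total > 0) {
      pool <- fungal[!fungal$sample_id %in% controls &
                       fungal$asv_id %in% cc$asv_id, , drop = FALSE]
      if (!is.null(run_of) && cid %in% names(run_of)) {
        pool <- pool[!is.na(run_of[pool$sample_id]) &
                       run_of[pool$sample_id] == run_of[[cid]], ,
                     drop = FALSE]
      }
      if (nrow(pool) > 0) {
        score <- pool |>
          dplyr::summarise(shared = sum(.data$reads), .by = "sample_id") |>
          dplyr::arrange(dplyr::desc(.data$shared), .data$sample_id)
        cand_id <- score$sample_id[1]
        cand_reads <- score$shared[1]
      }
    }
    tibble::tibble(sample_id = cid, fungal_reads = total,
                   n_units = nrow(cc), candidate_source = cand_id,
                   source_shared_reads = cand_reads)
  })
  class(rows) <- c("negctrl_report", class(rows))
  rows
}

#' Summary of a negative-control report
#'
#' @param x A `negctrl_report`.
#' @param ... Unused.
#' @return A tibble: `n_controls`, `n_zero` (controls with no fungal
#'   reads), `pct_zero` (rounded to the nearest percent).
#' @export
glance.negctrl_report <- function(x, ...) {
  n <- nrow(x)
  nz <- sum(x$fungal_reads == 0)
  tibble::tibble(n_controls = n, n_zero = nz,
                 pct_zero = if (n > 0) round(100 * nz / n) else NA_real_)
}
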