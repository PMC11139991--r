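#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline. Defaults are the
#' study-protocol values: 90% assignment probability for cluster cores,
#' 10,000-read depth threshold, 0.2 kingdom-match dissimilarity
#' (similarity 0.8), strict 0.9 spike similarity, k-mer prefilter 0.4 with
#' maximum alignment dissimilarity 0.6 and gap penalty 1, 1000-km
#' occurrence kernel.
#'
#' @param confidence Core assignment probability threshold.
#' @param depth_threshold Minimum per-sample reads.
#' @param kingdom_max_dissim Best-hit dissimilarity cutoff for kingdom
#'   classification.
#' @param spike_similarity Strict similarity cutoff for spike labelling.
#' @param max_dist Sparse-matrix dissimilarity cutoff.
#' @param kmer_prefilter Calibrated k-mer prefilter cutoff.
#' @param gap_penalty Internal gap-column penalty.
#' @param grid_step Threshold-optimization grid resolution.
#' @param correlation Null-model correlation type.
#' @param kernel_km Occurrence-kernel scale in km.
#' @param spike A [spike_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(confidence = 0.90, depth_threshold = 10000L,
                            kingdom_max_dissim = 0.2,
                            spike_similarity = 0.9, max_dist = 0.6,
                            kmer_prefilter = 0.4, gap_penalty = 1,
                            grid_step = 0.001,
                            correlation = c("pearson", "spearman"),
                            kernel_km = 1000, spike = spike_config()) {
  correlation <- match.arg(correlation)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full post-denoising pipeline
#'
#' End-to-end orchestration: collapse end-gap duplicate ASVs, label and
#' split spike reads, quantify per-sample DNA amounts, optimize clustering
#' thresholds on the reference database, cluster ASVs into species-level
#' OTUs across all ranks, classify kingdoms and purge non-fungal
#' pseudotaxa, and write the output tables (`metadata.csv`,
#' `otu.table.csv`, `taxonomy.csv`, `pseudophyla_fungi.csv`,
#' `pseudophyla_nonfungi.csv`) plus QC reports into `out_dir`. Outputs are
#' deterministic given identical inputs.
#'
#' @param bundle Input list: `asvs` (`asv_id`, `sequence`, `reads`),
#'   `counts` (long), `assignments`, `metadata`, `spike_refs`, and
#'   optionally `controls` (negative-control sample ids).
#' @param refs Annotated reference tibble (`sh_id`, `sequence`,
#'   lineage columns).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with all intermediate and final objects:
#'   `asvs`, `counts`, `hierarchy`, `kingdom_calls`, `removed`,
#'   `pseudophyla`, `thresholds`, `metadata`, `depth_report`,
#'   `negctrl_report`, `tables`.
#' @export
run_pipeline <- function(bundle, refs, out_dir = NULL,
                         cfg = pipeline_config()) {
  for (nm in c("asvs", "counts", "assignments", "metadata", "spike_refs")) {
    if (is.null(bundle[[nm]])) {
      stop("input bundle is missing '", nm, "'", call. = FALSE)
    }
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  # 1. end-gap duplicate collapse
  col <- step("collapse", collapse_end_gap_duplicates(
    bundle$asvs, counts = bundle$counts, gap_penalty = cfg$gap_penalty))
  asvs <- col$asvs
  rep_of <- setNames(col$map$representative, col$map$asv_id)
  counts <- bundle$counts |>
    dplyr::mutate(asv_id = unname(rep_of[.data$asv_id])) |>
    dplyr::summarise(reads = sum(.data$reads),
                     .by = c("sample_id", "asv_id"))
  assignments <- bundle$assignments |>
    dplyr::mutate(asv_id = unname(rep_of[.data$asv_id])) |>
    dplyr::arrange(.data$asv_id, .data$rank, dplyr::desc(.data$prob)) |>
    dplyr::distinct(.data$asv_id, .data$rank, .keep_all = TRUE)

  # 2. spike labelling
  asvs <- step("label_spikes", label_spikes(
    asvs, bundle$spike_refs, similarity_cutoff = cfg$spike_similarity))
  spike_ids <- asvs$asv_id[asvs$spike]
  study_counts <- counts[!counts$asv_id %in% spike_ids, , drop = FALSE]
  spike_counts <- counts[counts$asv_id %in% spike_ids, , drop = FALSE]

  # 3. DNA quantification
  metadata <- bundle$metadata
  per_sample <- tibble::tibble(`sample.id` = metadata$sample.id) |>
    dplyr::left_join(dplyr::summarise(study_counts,
                                      numnonspikes = sum(.data$reads),
                                      .by = "sample_id"),
                     by = c(sample.id = "sample_id")) |>
    dplyr::left_join(dplyr::summarise(spike_counts,
                                      numspikes = sum(.data$reads),
                                      .by = "sample_id"),
                     by = c(sample.id = "sample_id")) |>
    dplyr::mutate(dplyr::across(c("numnonspikes", "numspikes"),
                                ~ dplyr::coalesce(as.integer(.x), 0L)))
  metadata$numnonspikes <- per_sample$numnonspikes
  metadata$numspikes <- per_sample$numspikes
  q <- step("quantify", quantify_dna(metadata$numnonspikes,
                                     metadata$numspikes,
                                     metadata$spike_dilution,
                                     cfg = cfg$spike))
  metadata$dna_amount <- q$dna_amount

  # 4. QC
  sample_ids <- metadata$sample.id
  depth_report <- step("qc", filter_by_depth(
    counts[counts$sample_id %in% sample_ids, , drop = FALSE],
    threshold = cfg$depth_threshold))
  negctrl <- NULL
  if (length(bundle$controls %||% character(0)) > 0) {
    runs <- dplyr::bind_rows(
      tibble::tibble(sample_id = metadata$sample.id,
                     seqrun = metadata$seqrun),
      bundle$runs %||% NULL)
    negctrl <- step("qc", negative_control_report(
      counts, bundle$controls, runs = runs,
      spikes = asvs[, c("asv_id", "spike")]))
  }

  # 5. thresholds from the reference database
  ref_dist <- step("distmx", sparse_distances(
    refs[, c("sh_id", "sequence")], max_dist = cfg$max_dist,
    kmer_prefilter = cfg$kmer_prefilter, gap_penalty = cfg$gap_penalty))
  thresholds <- step("optimize-thresholds", build_threshold_table(
    refs, ref_dist, grid_step = cfg$grid_step, max_dist = cfg$max_dist))

  # 6. constrained clustering of non-spike ASVs
  nonspike <- asvs[!asvs$spike, c("asv_id", "sequence", "reads")]
  asv_dist <- step("distmx", sparse_distances(
    nonspike, max_dist = cfg$max_dist, kmer_prefilter = cfg$kmer_prefilter,
    gap_penalty = cfg$gap_penalty))
  hierarchy <- step("cluster", cluster_all_ranks(
    nonspike, assignments, asv_dist, thresholds,
    confidence = cfg$confidence))

  # 7. kingdom classification and pseudotaxon purge
  calls <- step("filter-kingdom", classify_kingdom(
    nonspike, refs, max_dissimilarity = cfg$kingdom_max_dissim))
  purged <- step("filter-kingdom", purge_pseudotaxa(hierarchy, calls))
  pseudo <- step("filter-kingdom", pseudophylum_tables(
    purged$hierarchy, purged$removed, calls))

  # 8. outputs
  retained_counts <- study_counts[
    study_counts$asv_id %in% purged$hierarchy$membership$asv_id &
      study_counts$sample_id %in% sample_ids, , drop = FALSE]
  tables <- step("write", build_output_tables(
    purged$hierarchy, retained_counts, samples = sample_ids))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metadata(metadata, file.path(out_dir, "metadata.csv"))
    step("write", write_outputs(purged$hierarchy, retained_counts, out_dir,
                                pseudophyla_fungi = pseudo$fungi,
                                pseudophyla_nonfungi = pseudo$nonfungi,
                                samples = sample_ids))
    write_threshold_table(thresholds, file.path(out_dir, "thresholds.csv"))
    readr::write_csv(depth_report, file.path(out_dir, "depth_report.csv"),
                     progress = FALSE)
    if (!is.null(negctrl)) {
      readr::write_csv(negctrl, file.path(out_dir, "negative_controls.csv"),
                       progress = FALSE)
    }
    writeLines(pipeline_log(bundle, cfg, purged$hierarchy),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(list(asvs = asvs, counts = counts, metadata = metadata,
                 depth_report = depth_report, negctrl_report = negctrl,
                 thresholds = thresholds, hierarchy = purged$hierarchy,
                 kingdom_calls = calls, removed = purged$removed,
                 pseudophyla = pseudo, tables = tables))
}

pipeline_log <- function(bundle, cfg, hierarchy) {
  par <- cfg[!vapply(cfg, is.list, logical(1))]
  c("pipeline run log",
    sprintf("input: %d ASVs, %d count rows, %d samples",
            nrow(bundle$asvs), nrow(bundle$counts), nrow(bundle$metadata)),
    sprintf("param %s = %s", names(par),
            vapply(par, function(x) paste(format(x), collapse = ","),
                   character(1))),
    sprintf("result: %d ASVs retained in %d OTUs",
            nrow(hierarchy$membership), nrow(hierarchy$otus)))
}

#' Write a simulated input bundle to disk
#'
#' Materializes the output of [simulate_dataset()] plus its references as
#' the file formats the pipeline consumes: FASTA for ASVs, references and
#' spikes, CSV for counts, assignments, metadata and occurrences, and the
#' ground-truth sidecar (never read by the pipeline).
#'
#' @param data Output of [simulate_dataset()].
#' @param refs Reference tibble from [simulate_references()].
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_input_bundle <- function(data, refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sequences(data$asvs[, c("asv_id", "sequence")],
                  file.path(dir, "asvs.fasta"))
  write_sequences(data$spike_refs[, c("spike_id", "sequence")],
                  file.path(dir, "spikes.fasta"))
  write_sequences(refs[, c("sh_id", "sequence")],
                  file.path(dir, "refs.fasta"))
  readr::write_csv(refs[, c("sh_id", tax_ranks())],
                   file.path(dir, "ref_taxonomy.csv"), progress = FALSE)
  readr::write_csv(data$counts, file.path(dir, "counts.csv"),
                   progress = FALSE)
  readr::write_csv(data$assignments, file.path(dir, "assignments.csv"),
                   progress = FALSE)
  write_metadata(data$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(
    tibble::tibble(species = data$occurrences$species,
                   decimalLatitude = data$occurrences$lat,
                   decimalLongitude = data$occurrences$lon),
    file.path(dir, "occurrences.csv"), progress = FALSE)
  writeLines(data$controls, file.path(dir, "controls.txt"))
  if (!is.null(data$runs)) {
    readr::write_csv(data$runs, file.path(dir, "runs.csv"), progress = FALSE)
  }
  readr::write_csv(data$truth, file.path(dir, "truth_synthetic.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' Counterpart of [write_input_bundle()].
#'
#' @param dir Directory containing the bundle files.
#' @return A list usable as `bundle`/`refs` in [run_pipeline()].
#' @export
read_input_bundle <- function(dir) {
  asvs <- read_sequences(file.path(dir, "asvs.fasta"), id_col = "asv_id")
  counts <- readr::read_csv(file.path(dir, "counts.csv"),
                            show_col_types = FALSE, progress = FALSE)
  totals <- dplyr::summarise(counts, reads = sum(.data$reads),
                             .by = "asv_id")
  asvs <- dplyr::left_join(asvs, totals, by = "asv_id") |>
    dplyr::mutate(reads = dplyr::coalesce(.data$reads, 0L))
  refs <- read_sequences(file.path(dir, "refs.fasta"), id_col = "sh_id") |>
    dplyr::left_join(readr::read_csv(file.path(dir, "ref_taxonomy.csv"),
                                     show_col_types = FALSE,
                                     progress = FALSE),
                     by = "sh_id")
  controls <- character(0)
  if (file.exists(file.path(dir, "controls.txt"))) {
    controls <- readLines(file.path(dir, "controls.txt"))
  }
  list(bundle = list(
         asvs = asvs, counts = counts,
         assignments = read_assignments(file.path(dir, "assignments.csv")),
         metadata = read_metadata(file.path(dir, "metadata.csv")),
         spike_refs = read_sequences(file.path(dir, "spikes.fasta"),
                                     id_col = "spike_id"),
         controls = controls,
         runs = if (file.exists(file.path(dir, "runs.csv")))
           readr::read_csv(file.path(dir, "runs.csv"),
                           show_col_types = FALSE, progress = FALSE)
         else NULL),
       refs = refs,
       occurrences = if (file.exists(file.path(dir, "occurrences.csv")))
         read_occurrences(file.path(dir, "occurrences.csv")) else NULL)
}
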