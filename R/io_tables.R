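#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble, uppercasing sequences and preserving the
#' record order of the file. Record ids must be unique and sequences
#' non-empty.
#'
#' @param path Path to a FASTA file.
#' @param id_col Name of the identifier column in the returned tibble.
#' @return A tibble with columns `id_col` and `sequence`.
#' @export
read_sequences <- function(path, id_col = "id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(id = ids, sequence = unname(seqs))
  names(out)[1] <- id_col
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame whose first column holds ids and which has a
#'   `sequence` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  assert_df_has(seqs, "sequence", "seqs")
  ss <- Biostrings::BStringSet(setNames(seqs$sequence, seqs[[1]]))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

metadata_fields <- function() {
  c("sample.id", "seqrun", "site", "date", "yday", "duration", "water",
    "insect", "unst.tweezers", "spike_dilution", "numnonspikes", "numspikes",
    "dna_amount", "lat", "lon", "temp.mean")
}

#' Read the sample metadata table
#'
#' Reads and validates `metadata.csv`. The schema has one row per sample and
#' the fields `sample.id`, `seqrun`, `site`, `date`, `yday`, `duration`,
#' `water`, `insect`, `unst.tweezers`, `spike_dilution`, `numnonspikes`,
#' `numspikes`, `dna_amount`, `lat`, `lon`, `temp.mean`. Missing water/insect
#' information is encoded as the merged level `"no.or.NA"`. `yday` is derived
#' from `date` when absent and checked for consistency when both are present.
#'
#' @param path Path to a metadata CSV file.
#' @return A validated tibble of sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(metadata_fields(), names(md))
  if (length(missing) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(md) == 0) return(md[, metadata_fields()])
  md <- dplyr::mutate(
    md,
    date = as.Date(.data$date),
    yday = as.integer(.data$yday),
    dplyr::across(dplyr::all_of(c("duration", "spike_dilution", "dna_amount",
                                  "lat", "lon", "temp.mean")), as.numeric),
    dplyr::across(dplyr::all_of(c("numnonspikes", "numspikes")), as.integer)
  )
  validate_metadata(md)
  md[, metadata_fields()]
}

validate_metadata <- function(md) {
  if (anyDuplicated(md$sample.id) > 0) {
    stop("duplicate sample.id in metadata", call. = FALSE)
  }
  bad_dil <- !is.na(md$spike_dilution) & !md$spike_dilution %in% c(0.01, 0.001)
  if (any(bad_dil)) {
    stop("spike_dilution outside {0.01, 0.001} for sample(s): ",
         paste(md$sample.id[bad_dil], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(md$date) & is.na(md$yday))) {
    stop("rows with neither a parseable date nor a yday", call. = FALSE)
  }
  both <- !is.na(md$date) & !is.na(md$yday)
  # yday capped at 365 (Dec 31 of a leap year maps to 365 in this schema)
  expect_yday <- pmin(as.integer(strftime(md$date[both], "%j")), 365L)
  if (any(md$yday[both] != expect_yday)) {
    stop("yday inconsistent with date for sample(s): ",
         paste(md$sample.id[both][md$yday[both] != expect_yday],
               collapse = ", "), call. = FALSE)
  }
  for (col in c("water", "insect")) {
    bad <- !is.na(md[[col]]) & !md[[col]] %in% c("yes", "no.or.NA")
    if (any(bad)) stop(col, " must be 'yes' or 'no.or.NA'", call. = FALSE)
  }
  bad_ll <- (!is.na(md$lat) & abs(md$lat) > 90) |
    (!is.na(md$lon) & abs(md$lon) > 180)
  if (any(bad_ll)) stop("latitude/longitude out of range", call. = FALSE)
  if (any(md$numnonspikes < 0, na.rm = TRUE) ||
      any(md$numspikes < 0, na.rm = TRUE)) {
    stop("negative read counts in metadata", call. = FALSE)
  }
  invisible(md)
}

#' Write the sample metadata table
#'
#' Serializes metadata with ISO-8601 dates, deriving `yday` from `date` where
#' absent, and collapsing missing water/insect information to `"no.or.NA"`.
#'
#' @param md A metadata tibble (see [read_metadata()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  assert_df_has(md, setdiff(metadata_fields(), "yday"), "metadata")
  if (!"yday" %in% names(md)) md$yday <- NA_integer_
  md <- dplyr::mutate(
    md,
    yday = ifelse(is.na(.data$yday) & !is.na(.data$date),
                  pmin(as.integer(strftime(as.Date(.data$date), "%j")), 365L),
                  as.integer(.data$yday)),
    water = ifelse(is.na(.data$water), "no.or.NA", .data$water),
    insect = ifelse(is.na(.data$insect), "no.or.NA", .data$insect),
    date = format(as.Date(.data$date))
  )
  readr::write_csv(md[, metadata_fields()], path, progress = FALSE)
  invisible(path)
}

#' Read probabilistic taxonomic assignments
#'
#' Long-format per-ASV taxonomic claims as produced by a probabilistic
#' classifier: one row per ASV x rank with a taxon name and a calibrated
#' probability.
#'
#' @param path Path to a CSV with columns `asv_id`, `rank`, `taxon`, `prob`.
#' @return A tibble of assignments.
#' @export
read_assignments <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_df_has(df, c("asv_id", "rank", "taxon", "prob"), "assignments")
  bad <- !df$rank %in% tax_ranks()
  if (any(bad)) {
    stop("unknown rank(s) in assignments: ",
         paste(unique(df$rank[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(df$prob < 0 | df$prob > 1, na.rm = TRUE)) {
    stop("assignment probabilities must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Read species occurrence records
#'
#' Reads the minimal column subset of the standard occurrence-record download
#' format: `species`, `decimalLatitude`, `decimalLongitude`.
#'
#' @param path Path to an occurrence CSV.
#' @return A tibble with columns `species`, `lat`, `lon`.
#' @export
read_occurrences <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_df_has(df, c("species", "decimalLatitude", "decimalLongitude"),
                "occurrences")
  out <- tibble::tibble(species = df$species,
                        lat = as.numeric(df$decimalLatitude),
                        lon = as.numeric(df$decimalLongitude))
  if (any(abs(out$lat) > 90 | abs(out$lon) > 180, na.rm = TRUE)) {
    stop("occurrence coordinates out of range", call. = FALSE)
  }
  out
}

#' Build the OTU and taxonomy tables from a cluster hierarchy
#'
#' Aggregates per-ASV read counts to species-level OTUs and recomputes
#' `nsample` (number of samples in which the OTU was found) and `nread`
#' (total reads) from the count table.
#'
#' @param hierarchy A `cluster_hierarchy` from [cluster_all_ranks()].
#' @param counts Long-format read counts: `sample_id`, `asv_id`, `reads`.
#' @param samples Optional character vector of all sample ids (so that
#'   samples with no reads still appear as all-zero rows).
#' @return A list with `otu_table` (rows = samples, columns = `sample.id`
#'   plus one column per OTU) and `taxonomy` (one row per OTU with lineage,
#'   `nsample`, `nread` and the representative `sequence`).
#' @export
build_output_tables <- function(hierarchy, counts, samples = NULL) {
  stopifnot(inherits(hierarchy, "cluster_hierarchy"))
  assert_df_has(counts, c("sample_id", "asv_id", "reads"), "counts")
  taxonomy <- hierarchy$otus
  membership <- hierarchy$membership
  unknown <- setdiff(unique(counts$asv_id), membership$asv_id)
  if (length(unknown) > 0) {
    stop("count table contains ASV(s) absent from the hierarchy: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  samples <- sort(unique(c(samples, counts$sample_id)))
  otu_of <- setNames(membership$otu_id, membership$asv_id)
  long <- counts |>
    dplyr::mutate(otu_id = unname(otu_of[.data$asv_id])) |>
    dplyr::summarise(reads = sum(.data$reads),
                     .by = c("sample_id", "otu_id"))
  wide <- long |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = "reads",
                       values_fill = 0L)
  wide <- wide[match(samples, wide$sample_id), , drop = FALSE]
  wide$sample_id <- samples
  wide[is.na(wide)] <- 0L
  missing_otu <- setdiff(taxonomy$otu_id, names(wide))
  for (o in missing_otu) wide[[o]] <- 0L
  wide <- wide[, c("sample_id", taxonomy$otu_id)]
  names(wide)[1] <- "sample.id"

  per_otu <- long |>
    dplyr::summarise(nread = sum(.data$reads),
                     nsample = dplyr::n_distinct(.data$sample_id[.data$reads > 0]),
                     .by = "otu_id")
  taxonomy <- taxonomy |>
    dplyr::left_join(per_otu, by = "otu_id") |>
    dplyr::mutate(nread = dplyr::coalesce(.data$nread, 0L),
                  nsample = dplyr::coalesce(.data$nsample, 0L))
  taxonomy <- taxonomy[, c("otu_id", "nsample", "nread", tax_ranks(),
                           "sequence")]
  names(taxonomy)[1] <- "OTU"
  list(otu_table = wide, taxonomy = taxonomy)
}

#' Write the pipeline's output files
#'
#' Writes `otu.table.csv` (rows = samples, columns = OTUs), `taxonomy.csv`
#' (one row per species-level OTU) and, when provided, the fungal and
#' non-fungal pseudophylum tables, into a directory. The four files are
#' linkable through sample ids and OTU ids.
#'
#' @param hierarchy A `cluster_hierarchy` from [cluster_all_ranks()].
#' @param counts Long-format read counts (`sample_id`, `asv_id`, `reads`).
#' @param dir Output directory (created if needed).
#' @param pseudophyla_fungi,pseudophyla_nonfungi Optional tibbles as built by
#'   [pseudophylum_tables()].
#' @param samples Optional character vector of all sample ids.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(hierarchy, counts, dir,
                          pseudophyla_fungi = NULL,
                          pseudophyla_nonfungi = NULL,
                          samples = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- build_output_tables(hierarchy, counts, samples = samples)
  paths <- c(otu_table = file.path(dir, "otu.table.csv"),
             taxonomy = file.path(dir, "taxonomy.csv"))
  readr::write_csv(tabs$otu_table, paths[["otu_table"]], progress = FALSE)
  readr::write_csv(tabs$taxonomy, paths[["taxonomy"]], progress = FALSE)
  if (!is.null(pseudophyla_fungi)) {
    paths[["pseudophyla_fungi"]] <- file.path(dir, "pseudophyla_fungi.csv")
    readr::write_csv(pseudophyla_fungi, paths[["pseudophyla_fungi"]],
                     progress = FALSE)
  }
  if (!is.null(pseudophyla_nonfungi)) {
    paths[["pseudophyla_nonfungi"]] <- file.path(dir,
                                                 "pseudophyla_nonfungi.csv")
    readr::write_csv(pseudophyla_nonfungi, paths[["pseudophyla_nonfungi"]],
                     progress = FALSE)
  }
  invisible(paths)
}
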