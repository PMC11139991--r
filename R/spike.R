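#' Label spike-derived ASVs
#'
#' Flags an ASV as a spike when its best-hit similarity to any synthetic
#' spike reference is strictly greater than `similarity_cutoff` (similarity
#' `s = 1 - d` with `d` the global-alignment dissimilarity of
#' [pairwise_dissimilarity()]).
#'
#' @param asvs Tibble `asv_id`, `sequence`.
#' @param spike_refs Tibble of spike reference sequences (first column ids,
#'   plus `sequence`).
#' @param similarity_cutoff Strict cutoff (default 0.9).
#' @return `asvs` with a logical `spike` column appended.
#' @export
label_spikes <- function(asvs, spike_refs, similarity_cutoff = 0.9) {
  assert_df_has(asvs, c("asv_id", "sequence"), "asvs")
  # strict "> cutoff" reading: a hit at exactly the cutoff is not a spike
  max_d <- 1 - similarity_cutoff
  hits <- nearest_reference(asvs[, c("asv_id", "sequence")], spike_refs,
                            max_dissimilarity = max_d)
  spike <- !is.na(hits$dist) & (1 - hits$dist) > similarity_cutoff
  dplyr::mutate(asvs, spike = spike[match(.data$asv_id, hits$query_id)])
}

#' Spike-in quantification configuration
#'
#' Parameters converting non-spike/spike read ratios into DNA amounts. The
#' calibration mass is the amount of spike DNA (ng) added per reaction at
#' the reference dilution; it comes from the companion wet-lab calibration
#' and is exposed here as configuration. All downstream comparisons in this
#' package are invariant to its numeric value.
#'
#' @param calib_mass Spike DNA mass (ng) per reaction at `dilution_ref`.
#' @param dilution_ref Reference dilution at which `calib_mass` applies.
#' @param air_volume Air volume per sample in m^3 (default 23.8, the
#'   24-hour cyclone throughput).
#' @return A list of class `spike_config`.
#' @export
spike_config <- function(calib_mass = 0.01, dilution_ref = 0.01,
                         air_volume = 23.8) {
  stopifnot(air_volume > 0, calib_mass > 0,
            dilution_ref %in% c(0.01, 0.001))
  structure(list(calib_mass = calib_mass, dilution_ref = dilution_ref,
                 air_volume = air_volume), class = "spike_config")
}

#' Semi-quantitative DNA amount from spike ratios
#'
#' Converts per-sample non-spike and spike read counts into
#' `log10(ng of fungal DNA per m^3 of air)`:
#' `amount = (numnonspikes / numspikes) * spike_mass / air_volume`, where
#' the spike mass added to the reaction is
#' `calib_mass * dilution / dilution_ref` (a 1:1000 reaction carries a
#' tenth of the spike DNA of a 1:100 reaction, which is what makes the
#' estimate invariant to the dilution level). Samples with zero spike reads
#' are unquantifiable; samples with zero non-spike reads are flagged as
#' containing no detectable fungal DNA.
#'
#' @param numnonspikes,numspikes Non-negative read counts (vectorized).
#' @param dilution Spike dilution per sample (0.01 or 0.001).
#' @param cfg A [spike_config()].
#' @return A tibble: `numnonspikes`, `numspikes`, `dilution`, `dna_amount`
#'   (log10 ng/m^3; `NA` when flagged) and `flag` (`"ok"`,
#'   `"unquantifiable"`, `"no_fungal_dna"`).
#' @export
quantify_dna <- function(numnonspikes, numspikes, dilution,
                         cfg = spike_config()) {
  if (any(numnonspikes < 0, na.rm = TRUE) ||
      any(numspikes < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(!dilution %in% c(0.01, 0.001))) {
    stop("dilution must be 0.01 or 0.001", call. = FALSE)
  }
  n <- max(length(numnonspikes), length(numspikes), length(dilution))
  numnonspikes <- rep_len(numnonspikes, n)
  numspikes <- rep_len(numspikes, n)
  dilution <- rep_len(dilution, n)
  amount <- (numnonspikes / numspikes) * cfg$calib_mass *
    (dilution / cfg$dilution_ref) / cfg$air_volume
  flag <- dplyr::case_when(
    numspikes == 0 ~ "unquantifiable",
    numnonspikes == 0 ~ "no_fungal_dna",
    TRUE ~ "ok"
  )
  tibble::tibble(numnonspikes = numnonspikes, numspikes = numspikes,
                 dilution = dilution,
                 dna_amount = ifelse(flag == "ok", log10(amount), NA_real_),
                 flag = flag)
}

#' Summarize a field test of sampling durations and blanks
#'
#' Computes per-group median DNA quantities and their fold difference
#' relative to a reference group, as used to compare 24-hour samples with
#' field blanks.
#'
#' @param data Tibble with a grouping column and a numeric DNA-quantity
#'   column.
#' @param group,value Column names (strings) of group and quantity.
#' @param reference The group against which fold differences are computed.
#' @return A tibble per group: `n`, `median`, `fold_vs_reference`.
#' @export
summarize_field_test <- function(data, group = "group", value = "dna_fg",
                                 reference) {
  assert_df_has(data, c(group, value), "data")
  out <- data |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data[[value]]),
                     .by = dplyr::all_of(group))
  ref_med <- out$median[out[[group]] == reference]
  if (length(ref_med) != 1) {
    stop("reference group not found: ", reference, call. = FALSE)
  }
  dplyr::mutate(out, fold_vs_reference = .data$median / ref_med)
}
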