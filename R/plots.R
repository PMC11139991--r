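#' Plot rarefaction curves
#'
#' @param curve Output of [rarefaction_curve()].
#' @return A ggplot: expected richness vs depth, one line per sample.
#' @export
plot_rarefaction <- function(curve) {
  assert_df_has(curve, c("sample_id", "depth", "richness"), "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth, y = .data$richness,
                                      group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "reads subsampled", y = "expected OTU richness") +
    ggplot2::theme_minimal()
}

#' Plot a depth report
#'
#' Histogram of per-sample sequencing depth with the filtering threshold.
#'
#' @param object A `depth_report` from [filter_by_depth()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total reads (fungal + spike)", y = "samples") +
    ggplot2::theme_minimal()
}

#' Plot a null-model result
#'
#' Histograms of empirical p-values and observed correlations across
#' species, with the uniform/zero null expectation drawn in red.
#'
#' @param object A `gssp_null` tibble from [null_model_all()].
#' @param ... Unused.
#' @return A ggplot (two panels via facetting).
#' @export
autoplot.gssp_null <- function(object, ...) {
  df <- object[!object$excluded, , drop = FALSE]
  long <- dplyr::bind_rows(
    tibble::tibble(metric = "p-value", value = df$p_value,
                   ref = 1 / 20), # uniform density over 20 bins
    tibble::tibble(metric = "correlation", value = df$r_obs, ref = NA_real_))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(
      .data$count / sum(.data$count))), bins = 20) +
    ggplot2::geom_hline(data = long[long$metric == "p-value", ][1, ],
                        ggplot2::aes(yintercept = .data$ref),
                        colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "fraction of species") +
    ggplot2::theme_minimal()
}

#' Plot an optimized threshold table
#'
#' Optimized single-linkage thresholds by subrank, one point per
#' supertaxon, sized by the number of reference sequences.
#'
#' @param object A `threshold_tbl` from [build_threshold_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_tbl <- function(object, ...) {
  df <- dplyr::mutate(object,
                      subrank = factor(.data$subrank,
                                       levels = tax_ranks()[-1]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subrank, y = .data$threshold)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_refs), alpha = 0.6) +
    ggplot2::labs(x = "clustered rank", y = "optimized threshold",
                  size = "references") +
    ggplot2::theme_minimal()
}
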