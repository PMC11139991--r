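#' Great-circle distance in kilometres
#'
#' Haversine distance with Earth radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distances in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range", call. = FALSE)
  }
  if (length(lat2) == 0 || length(lat1) == 0) return(numeric(0))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Distance-weighted occurrence index of a site
#'
#' `g_i = sum_occ exp(-d / kernel_km)` over all occurrence records, with
#' `d` the great-circle distance (km) between the site and the record. A
#' distance-weighted occurrence density: records at the site contribute 1,
#' far records contribute exponentially less.
#'
#' @param site_lat,site_lon Site coordinates (decimal degrees).
#' @param occ_lat,occ_lon Occurrence coordinates (vectors; may be empty).
#' @param kernel_km Kernel scale in km (default 1000).
#' @return The index `g_i` (a single non-negative number).
#' @export
gbif_index <- function(site_lat, site_lon, occ_lat, occ_lon,
                       kernel_km = 1000) {
  stopifnot(length(site_lat) == 1, length(site_lon) == 1,
            length(occ_lat) == length(occ_lon))
  if (length(occ_lat) == 0) return(0)
  d <- great_circle_km(site_lat, site_lon, occ_lat, occ_lon)
  sum(exp(-d / kernel_km))
}

#' Per-site occurrence indices for many species
#'
#' @param sites Tibble `site`, `lat`, `lon`.
#' @param occurrences Tibble `species`, `lat`, `lon` (see
#'   [read_occurrences()]).
#' @param kernel_km Kernel scale in km (default 1000).
#' @return A tibble `species` x `site` with column `g` (index 0 for species
#'   with no records).
#' @export
gbif_index_table <- function(sites, occurrences, kernel_km = 1000) {
  assert_df_has(sites, c("site", "lat", "lon"), "sites")
  assert_df_has(occurrences, c("species", "lat", "lon"), "occurrences")
  grid <- tidyr::expand_grid(species = unique(occurrences$species),
                             site = sites$site)
  occ_by_sp <- split(occurrences, occurrences$species)
  site_lat <- setNames(sites$lat, sites$site)
  site_lon <- setNames(sites$lon, sites$site)
  grid$g <- purrr::map2_dbl(grid$species, grid$site, function(sp, si) {
    o <- occ_by_sp[[sp]]
    gbif_index(site_lat[[si]], site_lon[[si]], o$lat, o$lon,
               kernel_km = kernel_km)
  })
  grid
}

undefined_cor <- function(x, y, min_pairs = 3L) {
  ok <- stats::complete.cases(x, y)
  sum(ok) < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
}

safe_cor <- function(x, y, method = "pearson", min_pairs = 3L) {
  if (undefined_cor(x, y, min_pairs)) return(NA_real_)
  stats::cor(x, y, use = "complete.obs", method = method)
}

#' Null-model consistency test of one species' distribution
#'
#' Correlates a focal species' per-site prevalence (fraction of samples in
#' which it was detected) with its distance-weighted occurrence index over
#' the same sites. The null distribution replaces the focal prevalence with
#' that of each non-focal species; the empirical p-value is the proportion
#' of defined null correlations strictly exceeding the observed one. The
#' correlation is undefined (species excluded) with fewer than 3 complete
#' pairs or when either vector has zero variance.
#'
#' @param focal_p Numeric vector: focal prevalence per site.
#' @param focal_g Numeric vector: occurrence index per site (same order).
#' @param nonfocal_p Matrix or data frame of non-focal prevalences, one
#'   column per non-focal species, rows aligned with `focal_p`.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r_obs`, `n_null` (defined null values),
#'   `p_value`, `excluded` (logical).
#' @export
consistency_test <- function(focal_p, focal_g, nonfocal_p,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  nonfocal_p <- as.matrix(nonfocal_p)
  if (length(focal_p) != length(focal_g) ||
      nrow(nonfocal_p) != length(focal_p)) {
    stop("site vectors are not aligned", call. = FALSE)
  }
  r_obs <- safe_cor(focal_p, focal_g, method)
  if (is.na(r_obs)) {
    return(tibble::tibble(r_obs = NA_real_, n_null = 0L,
                          p_value = NA_real_, excluded = TRUE))
  }
  null_vals <- apply(nonfocal_p, 2, safe_cor, y = focal_g, method = method)
  null_vals <- null_vals[!is.na(null_vals)]
  tibble::tibble(r_obs = r_obs, n_null = length(null_vals),
                 p_value = if (length(null_vals) > 0)
                   mean(null_vals > r_obs) else NA_real_,
                 excluded = FALSE)
}

#' Distribution-consistency null model over all species
#'
#' Runs [consistency_test()] for every species of a prevalence table
#' against shared occurrence indices.
#'
#' @param prevalence Tibble `species`, `site`, `p` (prevalence in `[0,1]`).
#' @param gbif_idx Tibble `species`, `site`, `g` (from
#'   [gbif_index_table()]). Species without rows get index 0 at all sites.
#' @param method Correlation type (default Pearson).
#' @return A `gssp_null` tibble: one row per species with `r_obs`,
#'   `n_null`, `p_value`, `excluded`.
#' @export
null_model_all <- function(prevalence, gbif_idx,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_df_has(prevalence, c("species", "site", "p"), "prevalence")
  assert_df_has(gbif_idx, c("species", "site", "g"), "gbif_idx")
  p_wide <- prevalence |>
    tidyr::pivot_wider(names_from = "species", values_from = "p") |>
    dplyr::arrange(.data$site)
  sites <- p_wide$site
  p_mat <- as.matrix(p_wide[, -1, drop = FALSE])
  g_wide <- gbif_idx |>
    tidyr::pivot_wider(names_from = "species", values_from = "g",
                       values_fill = 0)
  g_wide <- g_wide[match(sites, g_wide$site), , drop = FALSE]
  species <- colnames(p_mat)
  out <- purrr::map_dfr(species, function(sp) {
    g <- if (sp %in% names(g_wide)) g_wide[[sp]] else rep(0, length(sites))
    res <- consistency_test(p_mat[, sp], g,
                            p_mat[, setdiff(species, sp), drop = FALSE],
                            method = method)
    dplyr::bind_cols(tibble::tibble(species = sp), res)
  })
  class(out) <- c("gssp_null", class(out))
  out
}

#' Expected number of exceedances under a uniform p-value distribution
#'
#' If p-values were uniform on `[0, 1]`, the expected number of species
#' with `p > threshold` among `n_species` is
#' `round((1 - threshold) * n_species)`.
#'
#' @param n_species Number of tested species.
#' @param threshold Exceedance threshold in (0, 1).
#' @return An integer count.
#' @export
expected_uniform_exceedances <- function(n_species, threshold) {
  stopifnot(threshold > 0, threshold < 1, n_species >= 0)
  as.integer(round((1 - threshold) * n_species))
}

#' Summarize classifier-vs-expert agreement by confidence band
#'
#' Counts consistent and inconsistent classifications per classifier
#' confidence band and reports the percentage inconsistent (two decimals).
#' Bands follow the probabilistic classifier's convention: reliable
#' (probability >= 0.9), plausible (`[0.5, 0.9)`), best hit (`[0.01, 0.5)`)
#' and no hit.
#'
#' @param comparison Tibble with columns `band` and `consistent` (logical).
#' @return A tibble per band: `n_total`, `n_inconsistent`,
#'   `pct_inconsistent` (NA for empty bands).
#' @export
agreement_summary <- function(comparison) {
  assert_df_has(comparison, c("band", "consistent"), "comparison")
  comparison |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_inconsistent = sum(!.data$consistent),
                     .by = "band") |>
    dplyr::mutate(pct_inconsistent = ifelse(
      .data$n_total > 0,
      round(100 * .data$n_inconsistent / .data$n_total, 2), NA_real_))
}

#' Assign a classifier probability to its confidence band
#'
#' @param prob Probability of the best classification (NA = no hit).
#' @return Character vector: `"reliable"`, `"plausible"`, `"best_hit"` or
#'   `"no_hit"`.
#' @export
confidence_band <- function(prob) {
  dplyr::case_when(
    is.na(prob) | prob < 0.01 ~ "no_hit",
    prob >= 0.9 ~ "reliable",
    prob >= 0.5 ~ "plausible",
    TRUE ~ "best_hit"
  )
}
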