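#' Configuration for the synthetic-data generators
#'
#' Defines the conditions emulated by [simulate_references()] and
#' [simulate_dataset()]: a rank-structured fungal taxonomy whose sister
#' taxa diverge by strictly decreasing amounts from phylum down to species,
#' frequent intraspecific sequence variants, a site-by-week sampling design
#' with spike-in reads at the two study dilutions, non-fungal contaminants,
#' negative controls, and occurrence records clustered around the sites
#' where a species is prevalent.
#'
#' Divergences are the expected total dissimilarity between sister taxa at
#' each rank (so e.g. two congeneric species differ by about
#' `div["species"]`), and must decrease strictly from phylum to species and
#' then to `intraspecific`.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus
#'   Taxonomy shape.
#' @param divergence Named numeric vector of per-rank divergences.
#' @param intraspecific Expected dissimilarity among ASVs of one species.
#' @param seq_length Amplicon length (default 300, ITS2-like).
#' @param n_asvs_per_species,n_refs_per_species Variants per species.
#' @param unassigned_fraction Fraction of fungal ASVs without any
#'   classifier assignment.
#' @param partial_fraction Fraction of assigned ASVs whose assignment stops
#'   above species rank.
#' @param nonfungal_species,nonfungal_asvs_per_species Out-group
#'   contaminant load.
#' @param n_unknown_asvs ASVs with no relative anywhere in the references.
#' @param end_gap_fraction Fraction of fungal ASVs duplicated as terminal
#'   truncations (end-gap variants of an existing ASV).
#' @param n_sites,samples_per_week,n_weeks Sampling design (47 sites, two
#'   24-h samples per week).
#' @param mean_depth_log,sd_depth_log Log-scale parameters of per-sample
#'   sequencing depth.
#' @param spike_dilutions,early_dilution_fraction Spike dilution levels and
#'   the fraction of early samples run at the stronger dilution.
#' @param n_spikes Number of synthetic spike plasmids (default 9).
#' @param controls_per_run,samples_per_run Negative-control layout per
#'   sequencing run.
#' @param contaminated_control_fraction Fraction of controls receiving
#'   cross-contamination from a co-run sample.
#' @param occ_per_species Mean occurrence records per species.
#' @param occurrence_scale_km Spatial clustering scale of occurrence
#'   records around high-prevalence sites.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_phyla = 6L, classes_per_phylum = 2L,
                       orders_per_class = 1L, families_per_order = 1L,
                       genera_per_family = 2L, species_per_genus = 2L,
                       divergence = c(phylum = 0.32, class = 0.24,
                                      order = 0.18, family = 0.13,
                                      genus = 0.09, species = 0.05),
                       intraspecific = 0.01,
                       seq_length = 300L,
                       n_asvs_per_species = 2L, n_refs_per_species = 3L,
                       unassigned_fraction = 0.3,
                       partial_fraction = 0.15,
                       nonfungal_species = 4L,
                       nonfungal_asvs_per_species = 2L,
                       n_unknown_asvs = 3L,
                       end_gap_fraction = 0.05,
                       n_sites = 47L, samples_per_week = 2L, n_weeks = 29L,
                       mean_depth_log = log(60000), sd_depth_log = 0.8,
                       spike_dilutions = c(0.01, 0.001),
                       early_dilution_fraction = 0.12,
                       n_spikes = 9L,
                       controls_per_run = 3L, samples_per_run = 84L,
                       contaminated_control_fraction = 0.1,
                       occ_per_species = 40,
                       occurrence_scale_km = 300) {
  div <- divergence[cluster_ranks()]
  if (anyNA(div)) stop("divergence must name phylum..species", call. = FALSE)
  if (any(diff(c(div, intraspecific)) >= 0)) {
    stop("divergences must decrease strictly from phylum to species to ",
         "intraspecific", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$divergence <- div
  structure(cfg, class = "sim_config")
}

# substitute n random positions with a different base
mutate_seq <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(v), min(n_mut, length(v)))
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(bases, b), 1), character(1))
  paste(v, collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# per-branch mutation counts so that sister taxa at rank r end up at total
# divergence div[r]: branch at rank r adds (div[r] - div[r+1]) / 2
branch_muts <- function(cfg) {
  div <- c(unname(cfg$divergence), cfg$intraspecific) # phylum..species, leaf
  step <- (div[1:6] - div[2:7]) / 2
  round(cfg$seq_length * step)
}

#' Simulate a reference database with rank-structured divergence
#'
#' Evolves sequences down a balanced taxonomy tree by point substitutions,
#' with per-rank branch lengths chosen so realized inter-taxon distances
#' reproduce the configured sister-taxon divergences. Also generates
#' out-group (non-fungal) reference species, a couple of
#' kingdom-unspecified references, and synthetic spike plasmids.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `refs` (tibble `sh_id`, `sequence`, lineage columns),
#'   `species` (tibble of true species with lineage and ancestral
#'   sequence), `spike_refs` (tibble `spike_id`, `sequence`), and `cfg`.
#' @export
simulate_references <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ranks <- cluster_ranks() # phylum..species
  sizes <- c(cfg$n_phyla, cfg$classes_per_phylum, cfg$orders_per_class,
             cfg$families_per_order, cfg$genera_per_family,
             cfg$species_per_genus)
  muts <- branch_muts(cfg)
  prefix <- c("Phy", "Cls", "Ord", "Fam", "Gen", "Spc")

  nodes <- tibble::tibble(name = "Fungi", sequence = random_seq(cfg$seq_length))
  lineages <- list(c(kingdom = "Fungi"))
  for (lev in seq_along(ranks)) {
    new_nodes <- list()
    new_lin <- list()
    for (p in seq_len(nrow(nodes))) {
      for (k in seq_len(sizes[lev])) {
        nm <- sprintf("%s_%s%d", nodes$name[p], prefix[lev], k)
        new_nodes[[length(new_nodes) + 1]] <-
          tibble::tibble(name = nm,
                         sequence = mutate_seq(nodes$sequence[p], muts[lev]))
        lin <- lineages[[p]]
        lin[ranks[lev]] <- nm
        new_lin[[length(new_lin) + 1]] <- lin
      }
    }
    nodes <- dplyr::bind_rows(new_nodes)
    lineages <- new_lin
  }
  species <- dplyr::bind_cols(
    purrr::map_dfr(lineages, ~ tibble::as_tibble(as.list(.x))),
    nodes["sequence"]
  )

  leaf_mut <- round(cfg$seq_length * cfg$intraspecific / 2)
  refs <- purrr::map_dfr(seq_len(nrow(species)), function(i) {
    tibble::tibble(
      sequence = vapply(seq_len(cfg$n_refs_per_species),
                        function(k) mutate_seq(species$sequence[i], leaf_mut),
                        character(1)),
      dplyr::bind_rows(species[rep(i, cfg$n_refs_per_species), tax_ranks()])
    )
  })

  # out-group reference species from independent roots
  kingdoms <- rep(c("Viridiplantae", "Metazoa", "Alveolata"),
                  length.out = cfg$nonfungal_species)
  nonfungal <- purrr::map_dfr(seq_len(cfg$nonfungal_species), function(i) {
    root <- random_seq(cfg$seq_length)
    tibble::tibble(
      sequence = vapply(seq_len(cfg$n_refs_per_species),
                        function(k) mutate_seq(root, leaf_mut),
                        character(1)),
      kingdom = kingdoms[i], phylum = sprintf("%s_Phy%d", kingdoms[i], i),
      class = NA_character_, order = NA_character_, family = NA_character_,
      genus = NA_character_,
      species = sprintf("%s_Spc%d", kingdoms[i], i))
  })
  unspec <- tibble::tibble(
    sequence = vapply(1:2, function(k) random_seq(cfg$seq_length),
                      character(1)),
    kingdom = "unspecified", phylum = NA_character_, class = NA_character_,
    order = NA_character_, family = NA_character_, genus = NA_character_,
    species = NA_character_)
  refs <- dplyr::bind_rows(refs, nonfungal, unspec)
  refs <- dplyr::bind_cols(
    tibble::tibble(sh_id = sprintf("SH%05d", seq_len(nrow(refs)))), refs)

  spike_refs <- tibble::tibble(
    spike_id = sprintf("SYNSPIKE%02d", seq_len(cfg$n_spikes)),
    sequence = vapply(seq_len(cfg$n_spikes),
                      function(k) random_seq(cfg$seq_length), character(1)))

  check_divergence_structure(species, cfg)
  list(refs = refs, species = species, spike_refs = spike_refs, cfg = cfg)
}

# generation-time check that realized distances respect the configured
# rank ordering (sampled pairs)
check_divergence_structure <- function(species, cfg) {
  if (nrow(species) < 2 || cfg$species_per_genus < 2) return(invisible(TRUE))
  same_genus <- which(species$genus == species$genus[1])
  other_genus <- which(species$genus != species$genus[1] &
                         species$family == species$family[1])
  d_intra <- pairwise_dissimilarity(species$sequence[same_genus[1]],
                                    species$sequence[same_genus[2]])
  if (length(other_genus) > 0) {
    d_inter <- pairwise_dissimilarity(species$sequence[same_genus[1]],
                                      species$sequence[other_genus[1]])
    if (d_intra >= d_inter) {
      stop("realized divergences violate the configured rank ordering",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate a full input bundle for the pipeline
#'
#' Generates, from a reference set, everything the pipeline consumes:
#' ASVs (intraspecific variants per species, end-gap truncated duplicates,
#' non-fungal contaminants, sequences without any reference relative, spike
#' sequences), probabilistic taxonomic assignments with a configurable
#' unassigned fraction, a site-by-week count table with lognormal depths
#' and spike reads consistent with each sample's true DNA amount, sample
#' metadata, negative controls (mostly clean, occasionally
#' cross-contaminated from a co-run sample), clustered occurrence records,
#' and a ground-truth sidecar never read by the pipeline.
#'
#' @param sim Output of [simulate_references()].
#' @param spike_cfg A [spike_config()] used to back-calculate spike reads.
#' @return A list: `asvs` (`asv_id`, `sequence`, `reads`), `counts`
#'   (long format incl. spike ASVs and controls), `assignments`,
#'   `metadata`, `sites`, `occurrences`, `controls` (ids), `truth`
#'   (`asv_id`, true lineage, `true_otu`), `spike_refs`.
#' @export
simulate_dataset <- function(sim, spike_cfg = spike_config()) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 1L)
  species <- sim$species
  leaf_mut <- round(cfg$seq_length * cfg$intraspecific / 2)

  # --- ASVs -------------------------------------------------------------
  asv_rows <- purrr::map_dfr(seq_len(nrow(species)), function(i) {
    tibble::tibble(
      sequence = vapply(seq_len(cfg$n_asvs_per_species),
                        function(k) mutate_seq(species$sequence[i], leaf_mut),
                        character(1)),
      dplyr::bind_rows(species[rep(i, cfg$n_asvs_per_species), tax_ranks()]),
      origin = "fungal")
  })
  if (cfg$nonfungal_species > 0) {
    nf_kingdoms <- unique(sim$refs$kingdom[
      !sim$refs$kingdom %in% c("Fungi", "unspecified")])
    nf_refs <- sim$refs[sim$refs$kingdom %in% nf_kingdoms, , drop = FALSE]
    nf <- purrr::map_dfr(unique(nf_refs$species), function(sp) {
      base <- nf_refs$sequence[nf_refs$species == sp][1]
      tibble::tibble(
        sequence = vapply(seq_len(cfg$nonfungal_asvs_per_species),
                          function(k) mutate_seq(base, leaf_mut),
                          character(1)),
        kingdom = nf_refs$kingdom[nf_refs$species == sp][1],
        phylum = NA_character_, class = NA_character_, order = NA_character_,
        family = NA_character_, genus = NA_character_, species = sp,
        origin = "nonfungal")
    })
    asv_rows <- dplyr::bind_rows(asv_rows, nf)
  }
  if (cfg$n_unknown_asvs > 0) {
    unk <- tibble::tibble(
      sequence = vapply(seq_len(cfg$n_unknown_asvs),
                        function(k) random_seq(cfg$seq_length), character(1)),
      kingdom = NA_character_, phylum = NA_character_, class = NA_character_,
      order = NA_character_, family = NA_character_, genus = NA_character_,
      species = sprintf("unknown_%d", seq_len(cfg$n_unknown_asvs)),
      origin = "unknown")
    asv_rows <- dplyr::bind_rows(asv_rows, unk)
  }
  asv_rows$asv_id <- sprintf("ASV_%04d", seq_len(nrow(asv_rows)))

  # end-gap truncated duplicates of some fungal ASVs
  n_dup <- round(cfg$end_gap_fraction * sum(asv_rows$origin == "fungal"))
  dup_rows <- NULL
  if (n_dup > 0) {
    src <- sample(which(asv_rows$origin == "fungal"), n_dup)
    dup_rows <- asv_rows[src, , drop = FALSE]
    trim <- sample(3:10, n_dup, replace = TRUE)
    dup_rows$sequence <- substr(dup_rows$sequence, trim + 1,
                                nchar(dup_rows$sequence))
    dup_rows$origin <- "endgap_dup"
    dup_rows$parent_asv <- asv_rows$asv_id[src]
    dup_rows$asv_id <- sprintf("ASV_%04d",
                               nrow(asv_rows) + seq_len(n_dup))
    asv_rows <- dplyr::bind_rows(asv_rows, dup_rows)
  }
  if (!"parent_asv" %in% names(asv_rows)) asv_rows$parent_asv <- NA_character_

  # spike ASVs (observed exactly as the plasmid sequences)
  spike_asvs <- tibble::tibble(
    sequence = sim$spike_refs$sequence,
    kingdom = NA_character_, phylum = NA_character_, class = NA_character_,
    order = NA_character_, family = NA_character_, genus = NA_character_,
    species = sim$spike_refs$spike_id, origin = "spike",
    parent_asv = NA_character_,
    asv_id = sprintf("ASV_%04d", nrow(asv_rows) + seq_len(cfg$n_spikes)))
  asv_rows <- dplyr::bind_rows(asv_rows, spike_asvs)

  # --- assignments ------------------------------------------------------
  rank_probs <- c(phylum = 0.99, class = 0.985, order = 0.98, family = 0.975,
                  genus = 0.97, species = 0.96)
  fungal_idx <- which(asv_rows$origin %in% c("fungal", "endgap_dup"))
  assigned <- stats::runif(length(fungal_idx)) >= cfg$unassigned_fraction
  assignments <- purrr::map_dfr(fungal_idx[assigned], function(i) {
    depth <- 7L
    if (stats::runif(1) < cfg$partial_fraction) {
      depth <- sample(3:6, 1) # assignment stops above species
    }
    rk <- cluster_ranks()
    rk <- rk[seq_len(min(depth - 1L, length(rk)))]
    probs <- pmin(rank_probs[rk] - stats::runif(length(rk), 0, 0.05),
                  cummin(rank_probs[rk]))
    tibble::tibble(asv_id = asv_rows$asv_id[i], rank = rk,
                   taxon = unlist(asv_rows[i, rk]), prob = unname(probs))
  })

  # --- sites & samples --------------------------------------------------
  sites <- tibble::tibble(
    site = sprintf("S%02d", seq_len(cfg$n_sites)),
    lat = seq(-40, 70, length.out = cfg$n_sites) +
      stats::rnorm(cfg$n_sites, 0, 2),
    lon = stats::runif(cfg$n_sites, -180, 180),
    temp_mean = NA_real_)
  sites$lat <- pmax(pmin(sites$lat, 89), -89)
  sites$temp_mean <- 27 - 0.45 * abs(sites$lat) +
    stats::rnorm(cfg$n_sites, 0, 1.5)

  samples <- tidyr::expand_grid(site = sites$site,
                                week = seq_len(cfg$n_weeks),
                                rep = seq_len(cfg$samples_per_week)) |>
    dplyr::arrange(.data$week, .data$rep, .data$site) |>
    dplyr::mutate(sample_id = sprintf("%s_W%02dR%d", .data$site, .data$week,
                                      .data$rep))
  n_samp <- nrow(samples)
  samples$date <- as.Date("2019-01-07") + (samples$week - 1) * 7 +
    (samples$rep - 1) * 3
  n_early <- round(cfg$early_dilution_fraction * n_samp)
  samples$spike_dilution <- ifelse(seq_len(n_samp) <= n_early,
                                   cfg$spike_dilutions[1],
                                   cfg$spike_dilutions[2])

  # sequencing runs and negative controls
  run_no <- (seq_len(n_samp) - 1) %/% cfg$samples_per_run + 1
  samples$seqrun <- sprintf("RUN%03d", run_no)
  controls <- tidyr::expand_grid(seqrun = unique(samples$seqrun),
                                 k = seq_len(cfg$controls_per_run)) |>
    dplyr::mutate(sample_id = sprintf("%s_NEG%d", .data$seqrun, .data$k))

  # --- species ecology --------------------------------------------------
  sp_names <- species$species
  n_sp <- length(sp_names)
  optima <- stats::runif(n_sp, min(sites$temp_mean), max(sites$temp_mean))
  breadth <- stats::runif(n_sp, 4, 9)
  suit <- vapply(seq_len(n_sp),
                 function(i) exp(-((sites$temp_mean - optima[i]) /
                                     breadth[i])^2),
                 numeric(nrow(sites)))
  suit <- matrix(suit, nrow = nrow(sites))
  rownames(suit) <- sites$site
  detect <- stats::runif(n_sp, 0.25, 0.8) # per-sample detection if suitable
  abund_w <- stats::rlnorm(n_sp, 0, 1)    # species read-abundance weights

  asv_w <- stats::rlnorm(nrow(asv_rows), 0, 0.5) # within-species ASV weights
  fungal_like <- asv_rows$origin %in% c("fungal", "endgap_dup", "nonfungal",
                                        "unknown")
  asv_species <- asv_rows$species

  # contaminant/unknown "species" present at low uniform rate
  extra_sp <- setdiff(unique(asv_species[fungal_like]), sp_names)

  depths <- pmax(round(stats::rlnorm(n_samp, cfg$mean_depth_log,
                                     cfg$sd_depth_log)), 50)
  true_dna <- stats::rlnorm(n_samp, log(0.05), 1) # ng per m^3

  counts_list <- vector("list", n_samp)
  spike_mat <- matrix(0L, nrow = n_samp, ncol = cfg$n_spikes)
  numnonspikes <- integer(n_samp)
  for (s in seq_len(n_samp)) {
    si <- samples$site[s]
    present_sp <- sp_names[stats::runif(n_sp) < suit[si, ] * detect]
    present_extra <- extra_sp[stats::runif(length(extra_sp)) < 0.08]
    present <- c(present_sp, present_extra)
    idx <- which(fungal_like & asv_species %in% present)
    # spike reads from the true DNA amount via the spike model inverted
    dil <- samples$spike_dilution[s]
    ratio <- true_dna[s] * spike_cfg$air_volume /
      (spike_cfg$calib_mass * dil / spike_cfg$dilution_ref)
    n_non <- round(depths[s] * ratio / (1 + ratio))
    if (cfg$n_spikes == 0) n_non <- depths[s]
    n_spk <- depths[s] - n_non
    if (length(idx) == 0) n_non <- 0L
    if (n_non > 0) {
      wt <- asv_w[idx]
      spw <- abund_w[match(asv_species[idx], sp_names)]
      spw[is.na(spw)] <- 0.2
      wt <- wt * spw
      alloc <- stats::rmultinom(1, n_non, wt)[, 1]
      keep <- alloc > 0
      counts_list[[s]] <- tibble::tibble(
        sample_id = samples$sample_id[s],
        asv_id = asv_rows$asv_id[idx][keep],
        reads = as.integer(alloc[keep]))
    }
    if (n_spk > 0 && cfg$n_spikes > 0) {
      spike_mat[s, ] <- stats::rmultinom(1, n_spk,
                                         rep(1, cfg$n_spikes))[, 1]
    }
    numnonspikes[s] <- as.integer(n_non)
  }
  spike_counts <- tibble::tibble(
    sample_id = rep(samples$sample_id, cfg$n_spikes),
    asv_id = rep(spike_asvs$asv_id, each = n_samp),
    reads = as.integer(spike_mat))
  spike_counts <- spike_counts[spike_counts$reads > 0, , drop = FALSE]

  # negative controls: spike reads only, except an occasional contaminated
  # control that receives a scaled-down copy of a co-run sample's profile
  ctrl_list <- list()
  n_ctrl <- nrow(controls)
  contaminated <- stats::runif(n_ctrl) < cfg$contaminated_control_fraction
  for (k in seq_len(n_ctrl)) {
    cid <- controls$sample_id[k]
    if (cfg$n_spikes > 0) {
      spk <- stats::rmultinom(1, 2000, rep(1, cfg$n_spikes))[, 1]
      ctrl_list[[length(ctrl_list) + 1]] <- tibble::tibble(
        sample_id = cid, asv_id = spike_asvs$asv_id[spk > 0],
        reads = as.integer(spk[spk > 0]))
    }
    if (contaminated[k]) {
      donors <- samples$sample_id[samples$seqrun == controls$seqrun[k]]
      donor <- donors[sample.int(length(donors), 1)]
      dc <- counts_list[[match(donor, samples$sample_id)]]
      if (!is.null(dc) && nrow(dc) > 0) {
        leak <- dc[order(-dc$reads), , drop = FALSE]
        leak <- leak[seq_len(min(3, nrow(leak))), , drop = FALSE]
        leak$sample_id <- cid
        leak$reads <- pmax(1L, as.integer(round(leak$reads / 20)))
        ctrl_list[[length(ctrl_list) + 1]] <- leak
      }
    }
  }

  counts <- dplyr::bind_rows(c(counts_list, list(spike_counts), ctrl_list))

  # --- metadata ---------------------------------------------------------
  site_of <- setNames(sites$site, sites$site)
  metadata <- tibble::tibble(
    `sample.id` = samples$sample_id,
    seqrun = samples$seqrun,
    site = samples$site,
    date = samples$date,
    yday = pmin(as.integer(strftime(samples$date, "%j")), 365L),
    duration = 24,
    water = ifelse(stats::runif(n_samp) < 0.1, "yes", "no.or.NA"),
    insect = ifelse(stats::runif(n_samp) < 0.05, "yes", "no.or.NA"),
    `unst.tweezers` = ifelse(stats::runif(n_samp) < 0.02, "yes", "no"),
    spike_dilution = samples$spike_dilution,
    numnonspikes = numnonspikes,
    numspikes = as.integer(rowSums(spike_mat)),
    dna_amount = NA_real_,
    lat = sites$lat[match(samples$site, sites$site)],
    lon = sites$lon[match(samples$site, sites$site)],
    `temp.mean` = sites$temp_mean[match(samples$site, sites$site)])

  # --- occurrence records ----------------------------------------------
  prev <- counts |>
    dplyr::filter(.data$sample_id %in% samples$sample_id) |>
    dplyr::left_join(samples[, c("sample_id", "site")], by = "sample_id") |>
    dplyr::left_join(asv_rows[, c("asv_id", "species")], by = "asv_id") |>
    dplyr::filter(.data$species %in% sp_names) |>
    dplyr::distinct(.data$site, .data$sample_id, .data$species) |>
    dplyr::count(.data$site, .data$species)
  samples_per_site <- cfg$samples_per_week * cfg$n_weeks
  occurrences <- purrr::map_dfr(seq_len(n_sp), function(i) {
    sp <- sp_names[i]
    w <- setNames(rep(1e-3, cfg$n_sites), sites$site)
    pv <- prev[prev$species == sp, , drop = FALSE]
    w[pv$site] <- w[pv$site] + pv$n / samples_per_site
    n_occ <- stats::rpois(1, cfg$occ_per_species)
    if (n_occ == 0) return(NULL)
    pick <- sample(sites$site, n_occ, replace = TRUE, prob = w)
    jit <- cfg$occurrence_scale_km / 111
    tibble::tibble(
      species = sp,
      lat = pmax(pmin(sites$lat[match(pick, sites$site)] +
                        stats::rnorm(n_occ, 0, jit), 90), -90),
      lon = sites$lon[match(pick, sites$site)] + stats::rnorm(n_occ, 0, jit))
  })
  if (nrow(occurrences) > 0) {
    occurrences$lon <- ((occurrences$lon + 180) %% 360) - 180
  } else {
    occurrences <- tibble::tibble(species = character(0), lat = numeric(0),
                                  lon = numeric(0))
  }

  totals <- counts |>
    dplyr::summarise(reads = sum(.data$reads), .by = "asv_id")
  asvs <- asv_rows[, c("asv_id", "sequence")] |>
    dplyr::left_join(totals, by = "asv_id") |>
    dplyr::mutate(reads = dplyr::coalesce(.data$reads, 0L))

  truth <- dplyr::bind_cols(
    asv_rows[, c("asv_id", "origin", "parent_asv")],
    asv_rows[, tax_ranks()]) |>
    dplyr::mutate(true_otu = .data$species)

  samples$true_dna_log10 <- log10(true_dna) # ground truth, never consumed

  runs <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples$sample_id, seqrun = samples$seqrun),
    tibble::tibble(sample_id = controls$sample_id,
                   seqrun = controls$seqrun))

  list(asvs = asvs, counts = counts, assignments = assignments,
       metadata = metadata, sites = sites, occurrences = occurrences,
       controls = controls$sample_id, runs = runs, truth = truth,
       spike_refs = sim$spike_refs, samples = samples)
}
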