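test_that("depth filtering keeps samples at the threshold boundary", {
  counts <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    asv_id = rep(c("a", "b"), 3),
    reads = c(5000L, 4999L, 5000L, 5000L, 100L, 200L))
  rep <- filter_by_depth(counts)
  expect_equal(rep$kept, c(FALSE, TRUE, FALSE)) # 9999 / 10000 / 300
  g <- glance(rep)
  expect_equal(g$n_discarded, 2L)
  expect_equal(g$percent_discarded, round(100 * 2 / 3, 1))

  empty <- filter_by_depth(counts[0, ])
  expect_true(is.na(glance(empty)$percent_discarded))
})

test_that("analytic rarefaction matches its boundary identities", {
  expect_equal(rarefied_richness(c(50, 0, 0), 10), 1)
  v <- c(10, 5, 2, 1)
  expect_equal(rarefied_richness(v, sum(v)), 4)
  expect_error(rarefied_richness(v, sum(v) + 1), "exceeds")
  expect_equal(rarefied_richness(v, 0), 0)
})

test_that("analytic rarefaction matches a Monte-Carlo subsampling oracle", {
  set.seed(61)
  n_draws <- 20000
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    v <- as.integer(sample(1:30, k, replace = TRUE))
    m <- sample(seq_len(sum(v) - 1), 1)
    analytic <- rarefied_richness(v, m)
    pool <- rep(seq_along(v), v)
    draws <- replicate(n_draws,
                       length(unique(pool[sample.int(length(pool), m)])))
    se <- sd(draws) / sqrt(n_draws)
    expect_lt(abs(analytic - mean(draws)), max(3 * se, 1e-8))
  }
})

test_that("rarefied richness is monotone in depth and bounded", {
  v <- c(40, 12, 5, 3, 1, 1)
  depths <- c(1, 5, 10, 25, 62)
  vals <- vapply(depths, function(m) rarefied_richness(v, m), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= length(v)))
  curve <- rarefaction_curve(
    tibble::tibble(sample_id = "s1", asv_id = letters[1:6], reads = v),
    depths)
  expect_equal(curve$richness, vals)
})

test_that("negative controls are screened and sources traced", {
  counts <- dplyr::bind_rows(
    tibble::tibble(sample_id = "neg1", asv_id = "spike1", reads = 500L),
    tibble::tibble(sample_id = "neg2", asv_id = c("o1", "o2"),
                   reads = c(30L, 20L)),
    tibble::tibble(sample_id = "study1", asv_id = c("o1", "o2"),
                   reads = c(300L, 200L)),
    tibble::tibble(sample_id = "study2", asv_id = c("o1", "o3"),
                   reads = c(50L, 1000L)),
    tibble::tibble(sample_id = "study3", asv_id = c("o1", "o2"),
                   reads = c(400L, 500L)))
  runs <- tibble::tibble(
    sample_id = c("neg1", "neg2", "study1", "study2", "study3"),
    seqrun = c("R1", "R1", "R1", "R1", "R2"))
  spikes <- tibble::tibble(asv_id = c("spike1", "o1", "o2", "o3"),
                           spike = c(TRUE, FALSE, FALSE, FALSE))
  rep <- negative_control_report(counts, c("neg1", "neg2"), runs = runs,
                                 spikes = spikes)
  # spike-only control counts as zero fungal reads
  expect_equal(rep$fungal_reads[rep$sample_id == "neg1"], 0)
  g <- glance(rep)
  expect_equal(g$n_zero, 1L)
  expect_equal(g$pct_zero, 50)
  # candidate source: the co-run sample with the highest shared abundance
  # (study3 shares more but is in another run)
  expect_equal(rep$candidate_source[rep$sample_id == "neg2"], "study1")
  expect_error(negative_control_report(counts, "nope"), "unknown control")
})

test_that("a synthetic contaminated control flags its donor sample", {
  b <- small_sim(seed = 67, contaminated_control_fraction = 1)
  d <- b$data
  spikes <- tibble::tibble(
    asv_id = d$asvs$asv_id,
    spike = d$asvs$asv_id %in%
      d$truth$asv_id[d$truth$origin == "spike"])
  runs <- dplyr::bind_rows(
    tibble::tibble(sample_id = d$metadata$sample.id,
                   seqrun = d$metadata$seqrun),
    tibble::tibble(sample_id = d$controls,
                   seqrun = sub("_NEG\\d+$", "", d$controls)))
  rep <- negative_control_report(d$counts, d$controls, runs = runs,
                                 spikes = spikes)
  contaminated <- rep[rep$fungal_reads > 0, ]
  expect_gt(nrow(contaminated), 0)
  expect_true(all(!is.na(contaminated$candidate_source)))
  # donor and control share a sequencing run
  run_of <- setNames(runs$seqrun, runs$sample_id)
  expect_equal(unname(run_of[contaminated$candidate_source]),
               unname(run_of[contaminated$sample_id]))
})
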