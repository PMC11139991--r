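# Independent reference implementations used as oracles. These are written
# in plain R, separately from the package internals, and implement the same
# contracts from scratch.

# quadratic-time global alignment oracle: minimal cost (mismatch 1, gap
# column `gp`, terminal gaps penalized in construction), ties resolved by
# maximal matches then minimal gap columns, terminal-gap columns excluded
# from the reported statistics.
oracle_align_stats <- function(a, b, gp = 1) {
  if (b < a) { tmp <- a; a <- b; b <- tmp } # canonical order, as documented
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  cost <- matrix(0, m + 1, n + 1)
  mat <- matrix(0L, m + 1, n + 1)
  gap <- matrix(0L, m + 1, n + 1)
  dir <- matrix(0L, m + 1, n + 1)
  for (j in seq_len(n)) {
    cost[1, j + 1] <- j * gp; gap[1, j + 1] <- j; dir[1, j + 1] <- 3L
  }
  for (i in seq_len(m)) {
    cost[i + 1, 1] <- i * gp; gap[i + 1, 1] <- i; dir[i + 1, 1] <- 2L
  }
  better <- function(c1, m1, g1, c2, m2, g2) {
    # is candidate 1 strictly better than candidate 2?
    if (c1 != c2) return(c1 < c2)
    if (m1 != m2) return(m1 > m2)
    g1 < g2
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      eq <- x[i] == y[j]
      c1 <- cost[i, j] + !eq; m1 <- mat[i, j] + eq; g1 <- gap[i, j]
      c2 <- cost[i, j + 1] + gp; m2 <- mat[i, j + 1]; g2 <- gap[i, j + 1] + 1L
      c3 <- cost[i + 1, j] + gp; m3 <- mat[i + 1, j]; g3 <- gap[i + 1, j] + 1L
      cc <- c1; mm <- m1; gg <- g1; dd <- 1L
      if (better(c2, m2, g2, cc, mm, gg)) { cc <- c2; mm <- m2; gg <- g2; dd <- 2L }
      if (better(c3, m3, g3, cc, mm, gg)) { cc <- c3; mm <- m3; gg <- g3; dd <- 3L }
      cost[i + 1, j + 1] <- cc; mat[i + 1, j + 1] <- mm
      gap[i + 1, j + 1] <- gg; dir[i + 1, j + 1] <- dd
    }
  }
  cols <- integer(0) # 1 match, 0 mismatch, 2 gap; end to start
  i <- m; j <- n
  while (i > 0 || j > 0) {
    d <- dir[i + 1, j + 1]
    if (d == 1L) { cols <- c(cols, if (x[i] == y[j]) 1L else 0L); i <- i - 1; j <- j - 1 }
    else if (d == 2L) { cols <- c(cols, 2L); i <- i - 1 }
    else { cols <- c(cols, 2L); j <- j - 1 }
  }
  while (length(cols) > 0 && cols[1] == 2L) cols <- cols[-1]
  while (length(cols) > 0 && cols[length(cols)] == 2L) cols <- cols[-length(cols)]
  c(matches = sum(cols == 1L), mismatches = sum(cols == 0L),
    gapcols = sum(cols == 2L))
}

oracle_dissim <- function(a, b, gp = 1) {
  s <- oracle_align_stats(a, b, gp)
  ncol <- sum(s)
  if (ncol == 0) return(1)
  unname((s["mismatches"] + gp * s["gapcols"]) / ncol)
}

# naive multi-class F-measure: explicit loops over classes and clusters
oracle_fmeasure <- function(clusters, labels) {
  total <- 0
  n <- length(labels)
  for (cl in unique(labels)) {
    in_c <- labels == cl
    best <- 0
    for (k in unique(clusters)) {
      in_k <- clusters == k
      ov <- sum(in_c & in_k)
      if (ov == 0) next
      p <- ov / sum(in_k)
      r <- ov / sum(in_c)
      best <- max(best, 2 * p * r / (p + r))
    }
    total <- total + sum(in_c) / n * best
  }
  total
}

# connected components at threshold t via igraph (independent of the
# package's union-find)
oracle_components <- function(ids, distmx, t) {
  e <- distmx[distmx$dist <= t & distmx$id1 %in% ids & distmx$id2 %in% ids, ]
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(e) > 0) g <- igraph::add_edges(g, rbind(e$id1, e$id2))
  comp <- igraph::components(g)$membership[ids]
  setNames(as.integer(comp), ids)
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at_rate <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  k <- round(length(v) * rate)
  if (k > 0) {
    pos <- sample(seq_along(v), k)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), character(1))
  }
  paste(v, collapse = "")
}

# labelled reference set with intra-taxon divergence `a` and inter-taxon
# divergence `b` (a < b)
make_ref_set <- function(n_taxa, n_per, a, b, len = 200) {
  base <- rand_seq(len)
  out <- lapply(seq_len(n_taxa), function(t) {
    anc <- mutate_at_rate(base, b / 2)
    tibble::tibble(
      id = sprintf("t%02d_r%02d", t, seq_len(n_per)),
      sequence = vapply(seq_len(n_per),
                        function(k) mutate_at_rate(anc, a / 2), character(1)),
      label = sprintf("taxon%02d", t))
  })
  dplyr::bind_rows(out)
}

# tiny simulation bundle used by several test files
small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(seed = seed, n_sites = 5, n_weeks = 3,
                    classes_per_phylum = 1L, ...)
  sim <- simulate_references(cfg)
  list(cfg = cfg, sim = sim, data = simulate_dataset(sim))
}
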