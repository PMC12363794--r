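# Shared fixtures: small configs and independent mini-oracles.

quick_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_promoters = 500, n_cells = 300, n_genes = 200,
             n_clusters = 3, ...)
}

# Independent brute-force GSEA enrichment score: walk the ranked list one
# gene at a time, accumulating |stat|^p (normalized) at hits and
# -1/(N - n) at misses; return the extreme of the running sum, preferring
# the positive deviation when |max| and |min| tie exactly (the statistic's
# documented tie-break).
brute_es <- function(stats_sorted, hit_idx, p = 1) {
  N <- length(stats_sorted)
  n <- length(hit_idx)
  is_hit <- seq_len(N) %in% hit_idx
  w <- abs(stats_sorted)^p
  sw <- sum(w[is_hit])
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- run + if (is_hit[i]) {
      if (sw > 0) w[i] / sw else 1 / n
    } else {
      -1 / (N - n)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  unname(if (hi + lo >= -1e-9 * max(hi, -lo, 1)) hi else lo)
}

# Rank-based AUROC of a score separating positives from negatives
# (Mann-Whitney U / (n1 * n0)).
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Build a plate_grid directly from an inhibition matrix (noise-free raw
# luminescence with control scale 1000).
plate_from_inhibition <- function(inh, doses_a, doses_b) {
  plate_grid(list((1 - inh) * 1000), doses_a, doses_b)
}

ranked_20 <- function(seed = 7) {
  set.seed(seed)
  stats <- sort(rnorm(20, sd = 2), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:20)
  stats
}

fixture_table <- function() {
  # 10 proteins encoding the filter rules by hand
  m <- rbind(
    p01 = c(5, 5, 5, 5, 0, 0),      # passes everywhere, clean IgG -> venn hit
    p02 = c(4, 100, 50, 50, 0, 0),  # fails one bait replicate -> no venn hit
    p03 = c(50, 50, 50, 50, 6, 0),  # IgG-passing -> no venn hit
    p04 = c(100, 90, 95, 80, 1, 1), # strongly enriched -> fdr hit
    p05 = c(80, 0, 0, 0, 0, 0),     # detected in 1/4 samples -> no fdr hit
    p06 = c(0, 0, 0, 0, 0, 0),      # no information -> untested
    p07 = c(6, 6, 6, 6, 5, 5),      # balanced vs IgG -> not enriched
    p08 = c(60, 55, 0, 0, 0, 0),    # detected in 2/4, enriched -> fdr eligible
    p09 = c(3, 3, 3, 3, 0, 0),      # below venn threshold in all replicates
    p10 = c(0, 0, 0, 0, 50, 50))    # IgG only -> never a hit
  colnames(m) <- c(sprintf("bait:SKO:rep%d", 1:4), sprintf("IgG:SKO:rep%d", 1:2))
  spectral_counts(m)
}

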