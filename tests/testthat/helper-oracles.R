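# Independent oracles and shared fixtures for the test suite. Each oracle is
# a deliberately naive implementation kept separate from the package code
# paths it checks.

# Exact Wilcoxon rank-sum p-value by full enumeration of all C(n+m, n)
# group labelings (tie-free inputs only).
wilcox_enum_p <- function(x, y, alternative) {
  n <- length(x)
  pool <- c(x, y)
  ranks <- rank(pool)
  W_obs <- sum(ranks[seq_len(n)])
  combos <- utils::combn(length(pool), n)
  Ws <- apply(combos, 2L, function(idx) sum(ranks[idx]))
  p_less <- mean(Ws <= W_obs)
  p_greater <- mean(Ws >= W_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

# Brute-force quantile normalization: sort/average, then average the
# reference values over tie blocks.
qn_oracle <- function(mat) {
  sorted <- apply(mat, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = nrow(mat))
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    vals <- numeric(nrow(mat))
    vals[order(mat[, j])] <- ref
    for (v in unique(mat[, j])) {
      idx <- mat[, j] == v
      vals[idx] <- mean(vals[idx])
    }
    out[, j] <- vals
  }
  out
}

# Naive complete-linkage agglomeration returning the merge heights in merge
# order (unique when all inter-cluster distances are distinct).
complete_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Small handcrafted count set: 4 endogenous, 2 housekeeping, 2 positive,
# 5 negative probes over `n` samples.
tiny_rcc_set <- function(n = 3L, seed = 42L) {
  set.seed(seed)
  counts <- rbind(
    matrix(rpois(4L * n, 300), nrow = 4L),
    matrix(rpois(2L * n, 800), nrow = 2L),
    matrix(rpois(2L * n, 5000), nrow = 2L),
    matrix(rpois(5L * n, 8), nrow = 5L)
  )
  rownames(counts) <- c("GZMA", "PRF1", "FOXP3", "IMM0001", "HK001", "HK002",
                        "POS_A", "POS_B", "NEG_A", "NEG_B", "NEG_C", "NEG_D",
                        "NEG_E")
  rcc_set(counts, c(rep("Endogenous", 4L), rep("Housekeeping", 2L),
                    rep("Positive", 2L), rep("Negative", 5L)))
}

# Score the T-cell signature of a freshly simulated 125-sample cohort and
# return scores plus labels — the workhorse of the calibration checks.
simulate_and_score <- function(seed, effect_map = list()) {
  cfg <- simulation_config(n_samples = 125L, recurrence_fraction = 0.2,
                           effect_map = effect_map, seed = seed)
  cohort <- simulate_counts(build_panel(cfg), cfg)
  norm <- log2_quantile_normalize(
    positive_control_normalize(background_floor(cohort$raw)))
  scores <- score_signatures(norm, cohort$signatures,
                             kinds = c("cell_type", "response_category"))
  list(scores = scores, recurrent = cohort$annotation$recurrent,
       cohort = cohort, norm = norm)
}
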