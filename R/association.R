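#' Wilcoxon rank-sum test
#'
#' Two-group rank-sum comparison reporting the rank-sum statistic W of `x`
#' (midranks for ties). The p-value is exact — full enumeration of the
#' `choose(n + m, n)` labelings — when the combined sample size does not
#' exceed `exact_cutoff` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two_sided"`, `"less"` (x shifted below y) or
#'   `"greater"`.
#' @param exact_cutoff Largest combined sample size for the exact null
#'   distribution (default 12).
#' @return List with `W` (rank-sum of `x`), `p`, `exact` flag, the
#'   alternative and the group sizes.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater"),
                              exact_cutoff = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n <- length(x)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n + length(y)) <= exact_cutoff && !ties
  alt <- c(two_sided = "two.sided", less = "less", greater = "greater")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt[[alternative]], exact = use_exact,
                correct = TRUE)
  )
  W <- sum(rank(c(x, y))[seq_len(n)])
  list(W = W, p = unname(ht$p.value), exact = use_exact,
       alternative = alternative, n = n, m = length(y))
}

#' Difference of mean Z scores between recurrent and non-recurrent samples
#'
#' @param ztable Samples-by-signatures matrix of standardized scores
#'   ([standardize_scores()]).
#' @param recurrent Logical vector (one value per sample, same order as the
#'   rows of `ztable`); both groups must be non-empty.
#' @return Named numeric vector: per-signature
#'   `mean(Z | recurrent) - mean(Z | non-recurrent)`.
#' @export
mean_z_difference <- function(ztable, recurrent) {
  stopifnot(is.matrix(ztable), length(recurrent) == nrow(ztable))
  recurrent <- as.logical(recurrent)
  if (!any(recurrent) || all(recurrent)) {
    stop("both recurrence groups must be non-empty", call. = FALSE)
  }
  colMeans(ztable[recurrent, , drop = FALSE]) -
    colMeans(ztable[!recurrent, , drop = FALSE])
}

#' Per-signature recurrence association report
#'
#' For every signature column: the mean-Z difference (recurrent minus
#' non-recurrent), the Wilcoxon rank-sum statistic of the recurrent group,
#' two-sided and one-sided ("less": recurrent scores lower) p-values, and
#' BH q-values across signatures (computed on the two-sided p; the headline
#' readout remains the raw p, which is what the score comparisons report).
#'
#' @param scores Samples-by-signatures score matrix (raw, not standardized).
#' @param recurrent Logical per-sample recurrence labels.
#' @param exact_cutoff Passed to [wilcoxon_rank_sum()].
#' @return data.frame with columns `signature`, `mean_z_diff`, `W`,
#'   `p_two_sided`, `p_one_sided_less`, `q`.
#' @export
signature_association <- function(scores, recurrent, exact_cutoff = 12L) {
  stopifnot(is.matrix(scores))
  recurrent <- as.logical(recurrent)
  z <- standardize_scores(scores)
  dz <- mean_z_difference(z, recurrent)
  tests <- lapply(colnames(scores), function(sig) {
    xr <- scores[recurrent, sig]
    xn <- scores[!recurrent, sig]
    two <- wilcoxon_rank_sum(xr, xn, "two_sided", exact_cutoff)
    less <- wilcoxon_rank_sum(xr, xn, "less", exact_cutoff)
    c(W = two$W, p2 = two$p, p1 = less$p)
  })
  tests <- do.call(rbind, tests)
  data.frame(
    signature = colnames(scores),
    mean_z_diff = unname(dz),
    W = tests[, "W"],
    p_two_sided = tests[, "p2"],
    p_one_sided_less = tests[, "p1"],
    q = bh_fdr(tests[, "p2"]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' reported in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Filter differential-expression records on fold change and FDR
#'
#' A gene is reported when its linear fold change exceeds the threshold in
#' either direction (`max(FC, 1/FC) > fc_threshold`, strict) and its BH
#' q-value is below `fdr_threshold` (strict).
#'
#' @param records data.frame with columns `fold_change` and `q` (as returned
#'   by [deg_table()]).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.3).
#' @return The reported subset of `records`, with the `reported` flag
#'   refreshed.
#' @export
deg_filter <- function(records, fc_threshold = 1.5, fdr_threshold = 0.3) {
  stopifnot(all(c("fold_change", "q") %in% names(records)))
  fc <- records$fold_change
  keep <- pmax(fc, 1 / fc) > fc_threshold & records$q < fdr_threshold
  records$reported <- keep
  records[keep, , drop = FALSE]
}

#' Differential expression table with moderated t statistics
#'
#' Runs the empirical-Bayes moderated t ([moderated_t()]) on the log2
#' matrix, attaches linear-scale group means and fold change (ratio of the
#' group means of anti-logged values — the default; set
#' `fc_scale = "log2"` to use `2^log2FC` instead), BH q-values, and the
#' reported flag of [deg_filter()].
#'
#' @param mat Gene-by-sample log2 expression matrix.
#' @param recurrent Logical per-sample labels.
#' @param fc_threshold,fdr_threshold Reporting thresholds (1.5 and 0.3).
#' @param fc_scale `"linear"` (ratio of linear-scale group means) or
#'   `"log2"` (anti-logged difference of log2 means).
#' @return data.frame, one row per gene: group means on both scales, fold
#'   change, log2FC, moderated `t`, `p`, `q`, `reported`.
#' @export
deg_table <- function(mat, recurrent, fc_threshold = 1.5, fdr_threshold = 0.3,
                      fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  recurrent <- as.logical(recurrent)
  mt <- moderated_t(mat, recurrent)
  lin1 <- rowMeans(2^mat[, recurrent, drop = FALSE])
  lin2 <- rowMeans(2^mat[, !recurrent, drop = FALSE])
  fc <- if (fc_scale == "linear") unname(lin1 / lin2) else 2^mt$log2fc
  out <- data.frame(
    gene = mt$gene,
    mean_log2_recurrent = mt$mean_g1,
    mean_log2_nonrecurrent = mt$mean_g2,
    mean_linear_recurrent = unname(lin1),
    mean_linear_nonrecurrent = unname(lin2),
    fold_change = fc,
    log2fc = mt$log2fc,
    t = mt$t,
    p = mt$p,
    q = bh_fdr(mt$p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$reported <- pmax(out$fold_change, 1 / out$fold_change) > fc_threshold &
    out$q < fdr_threshold
  attr(out, "prior") <- attr(mt, "prior")
  attr(out, "fc_scale") <- fc_scale
  out
}
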