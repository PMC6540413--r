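#' Floor counts below the background detection limit
#'
#' For each sample, background is estimated from the spiked-in negative
#' control probes: counts of endogenous and housekeeping probes below
#' `mean(neg) + 2 * sd(neg)` are considered below the limit of detection and
#' replaced by `mean(neg)`. The SD is the sample SD (n - 1 denominator).
#' Control probes are left untouched.
#'
#' @param raw An [rcc_set()] with at least 2 Negative probes.
#' @return The floored `rcc_set`; provenance gains `"background_floored"`.
#' @export
background_floor <- function(raw) {
  stopifnot(inherits(raw, "rcc_set"))
  neg <- class_rows(raw, "Negative")
  if (length(neg) < 2L) {
    stop("background flooring requires >= 2 Negative probes ",
         "(the background SD is undefined otherwise)", call. = FALSE)
  }
  bio <- class_rows(raw, c("Endogenous", "Housekeeping"))
  counts <- raw$counts
  for (j in seq_len(ncol(counts))) {
    m <- mean(counts[neg, j])
    s <- sd(counts[neg, j])
    low <- counts[bio, j] < m + 2 * s
    counts[bio[low], j] <- m
  }
  out <- raw
  out$counts <- counts
  out$provenance <- c(raw$provenance, "background_floored")
  out
}

#' Positive-control normalization
#'
#' Computes for each sample the geometric mean of its positive-control
#' counts; the scaling factor of sample j is the cohort arithmetic mean of
#' those geometric means divided by sample j's geometric mean. The factor is
#' applied to Endogenous, Housekeeping and Positive probes (so post-scaling
#' positive-control geometric means are identical across samples); negative
#' controls, which measure additive background, are not scaled.
#'
#' @param raw An [rcc_set()] with >= 1 Positive probe.
#' @param pseudo_count Optional escape hatch for zero positive-control
#'   counts: added to positive counts before the geometric mean (default 0,
#'   i.e. a zero positive count is an error).
#' @return The scaled `rcc_set` with attribute-like element `norm_factors`
#'   (named per-sample factors); provenance gains `"positive_normalized"`.
#' @export
positive_control_normalize <- function(raw, pseudo_count = 0) {
  stopifnot(inherits(raw, "rcc_set"))
  pos <- class_rows(raw, "Positive")
  if (length(pos) < 1L) stop("no Positive control probes", call. = FALSE)
  posmat <- raw$counts[pos, , drop = FALSE] + pseudo_count
  if (any(posmat <= 0)) {
    stop("zero positive-control count; geometric mean undefined ",
         "(set pseudo_count > 0 to override)", call. = FALSE)
  }
  geo <- exp(colMeans(log(posmat)))
  factors <- mean(geo) / geo
  scaled <- class_rows(raw, c("Endogenous", "Housekeeping", "Positive"))
  out <- raw
  out$counts[scaled, ] <- sweep(raw$counts[scaled, , drop = FALSE], 2L,
                                factors, `*`)
  out$norm_factors <- setNames(factors, raw$samples)
  out$provenance <- c(raw$provenance, "positive_normalized")
  out
}

#' Classical quantile normalization
#'
#' Each column's values are replaced, rank for rank, by the mean across
#' columns of the sorted values (the reference distribution). Ties within a
#' column receive the mean of the reference values over their tied ranks, so
#' the result is deterministic and invariant to input permutation.
#'
#' @param mat Numeric matrix (rows features, columns samples).
#' @return Matrix of the same shape; all columns share the same sorted value
#'   multiset.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  sorted <- apply(mat, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = nrow(mat))
  ref <- rowMeans(sorted)
  cref <- cumsum(ref)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    lo <- rank(mat[, j], ties.method = "min")
    hi <- rank(mat[, j], ties.method = "max")
    out[, j] <- (cref[hi] - c(0, cref)[lo]) / (hi - lo + 1)
  }
  out
}

#' Log2-transform and quantile-normalize an expression set
#'
#' Applies `log2` elementwise to the Endogenous and Housekeeping probes and
#' quantile-normalizes the resulting columns; control probes are dropped
#' from the output gene space.
#'
#' @param raw An [rcc_set()]; all Endogenous/Housekeeping values must be
#'   strictly positive (guaranteed after [background_floor()] whenever the
#'   negative-control mean is nonzero) unless an `offset` is supplied.
#' @param offset Non-negative value added before the log (default 0).
#' @return Gene-by-sample numeric matrix of normalized log2 values with
#'   attribute `provenance` extended by `"log2"` and
#'   `"quantile_normalized"`.
#' @export
log2_quantile_normalize <- function(raw, offset = 0) {
  stopifnot(inherits(raw, "rcc_set"), offset >= 0)
  bio <- class_rows(raw, c("Endogenous", "Housekeeping"))
  x <- raw$counts[bio, , drop = FALSE] + offset
  if (any(x <= 0)) {
    stop("non-positive expression value; log2 undefined ",
         "(floor the background or set offset > 0)", call. = FALSE)
  }
  out <- quantile_normalize(log2(x))
  attr(out, "provenance") <- c(raw$provenance, "log2", "quantile_normalized")
  out
}
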