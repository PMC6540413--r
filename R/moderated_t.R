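# Empirical-Bayes moderated two-group t statistics.
#
# Per gene g with group sizes n1, n2 and pooled residual variance s_g^2 on
# d_g = n1 + n2 - 2 df, the gene variances are shrunk toward a prior
# (d0, s0^2) estimated by method of moments on log s_g^2 (the scaled
# F / log-chi-square moment identities with digamma/trigamma corrections):
#
#   s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)
#   t~_g   = log2FC_g / (s~_g * sqrt(1/n1 + 1/n2)),   df = d0 + d_g
#
# d0 = 0 recovers the ordinary pooled t; d0 = Inf gives every gene the
# shared variance s0^2.

# Solve trigamma(y) = x by Newton iteration (monotone, well-conditioned on
# the transformed scale used below).
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior (d0, s0^2) from gene-level variances
#'
#' Method-of-moments fit on `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' the excess of `var(e)` over `trigamma(d_g/2)` determines the prior df
#' `d0` via the inverse trigamma; when there is no excess the prior df is
#' infinite and all genes share `s0^2`.
#'
#' @param s2 Per-gene residual variances (non-negative). Zero variances are
#'   excluded from estimation with a warning.
#' @param df Residual degrees of freedom (single value, > 0).
#' @return List with `d0` (possibly `Inf`) and `s0_2`.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(df > 0)
  pos <- s2 > 0
  if (!all(pos)) {
    warning(sum(!pos), " zero-variance gene(s) excluded from prior ",
            "estimation", call. = FALSE)
    s2 <- s2[pos]
  }
  if (length(s2) < 2L) {
    stop("need >= 2 genes with positive variance to estimate the prior",
         call. = FALSE)
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t test for a two-group contrast
#'
#' @param mat Gene-by-sample log2 expression matrix with gene rownames.
#' @param recurrent Logical per-sample labels; each group needs >= 2
#'   samples so every gene has positive residual df.
#' @param d0 Optional forced prior df: `0` gives the ordinary pooled
#'   two-sample t, `Inf` shares a single variance across genes (then `s0_2`
#'   must be supplied or estimable); default `NULL` estimates the prior via
#'   [fit_variance_prior()].
#' @param s0_2 Optional forced prior variance (used with finite or infinite
#'   `d0`; estimated when `NULL`).
#' @return data.frame per gene: `gene`, group means `mean_g1` (recurrent)
#'   and `mean_g2`, `log2fc = mean_g1 - mean_g2`, posterior variance
#'   `s2_post`, moderated `t`, total `df`, two-sided `p`. The prior is
#'   attached as attribute `prior`.
#' @export
moderated_t <- function(mat, recurrent, d0 = NULL, s0_2 = NULL) {
  stopifnot(is.matrix(mat))
  recurrent <- as.logical(recurrent)
  if (length(recurrent) != ncol(mat)) {
    stop("labels must match the number of samples", call. = FALSE)
  }
  n1 <- sum(recurrent)
  n2 <- sum(!recurrent)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs >= 2 samples (residual variance undefined ",
         "otherwise)", call. = FALSE)
  }
  g1 <- mat[, recurrent, drop = FALSE]
  g2 <- mat[, !recurrent, drop = FALSE]
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  dg <- n1 + n2 - 2L
  s2 <- (rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / dg

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
  } else if (is.infinite(d0)) {
    prior <- list(d0 = Inf,
                  s0_2 = if (is.null(s0_2)) fit_variance_prior(s2, dg)$s0_2
                         else s0_2)
  } else {
    prior <- list(d0 = d0, s0_2 = if (is.null(s0_2)) {
      if (d0 > 0) fit_variance_prior(s2, dg)$s0_2 else 0
    } else {
      s0_2
    })
  }

  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (prior$d0 * prior$s0_2 + dg * s2) / (prior$d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tstat <- lfc / se
  df_total <- prior$d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene = rownames(mat),
    mean_g1 = unname(m1),
    mean_g2 = unname(m2),
    log2fc = unname(lfc),
    s2_post = unname(s2_post),
    t = unname(tstat),
    df = df_total,
    p = unname(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "prior") <- prior
  out
}
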