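#' Aggregate per-slide TIL foci counts into the 0-4 morphologic score
#'
#' The morphologic tumor-infiltrating lymphocyte score of a patient is the
#' maximum number of lymphocyte/plasma-cell foci seen on any H&E slide of
#' that tumor, capped at 4 (4 or more foci score 4). A patient with slides
#' showing 2 and 3 foci therefore scores 3.
#'
#' @param foci Integer vector of per-slide foci counts; at least one slide
#'   (no imputation for patients without slides).
#' @return Integer score in 0..4.
#' @export
aggregate_til_score <- function(foci) {
  if (length(foci) == 0L) {
    stop("no slides: TIL score undefined", call. = FALSE)
  }
  foci <- as.integer(foci)
  if (any(is.na(foci)) || any(foci < 0L)) {
    stop("foci counts must be non-negative integers", call. = FALSE)
  }
  min(max(foci), 4L)
}

#' Dichotomize a morphologic TIL score
#'
#' Two published cut-offs: `cut2` calls scores 2-4 high (0-1 low), `cut3`
#' calls 3-4 high (0-2 low).
#'
#' @param score Integer score(s) in 0..4.
#' @param scheme `"cut2"` or `"cut3"`.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(score, scheme = c("cut2", "cut3")) {
  scheme <- match.arg(scheme)
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 0L) || any(score > 4L)) {
    stop("TIL scores must lie in 0..4", call. = FALSE)
  }
  cut <- if (scheme == "cut2") 2L else 3L
  factor(ifelse(score >= cut, "high", "low"), levels = c("low", "high"))
}

#' Build a 2x2 contingency table
#'
#' Cell layout: `a` exposed with event, `b` exposed without, `c` unexposed
#' with event, `d` unexposed without.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Matrix of class `contingency_2x2` (rows exposed/unexposed,
#'   columns event/no_event).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cells must be non-negative counts", call. = FALSE)
  }
  m <- matrix(cells, nrow = 2L, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no_event")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Odds ratio with Woolf confidence interval and chi-square test
#'
#' `OR = (a * d) / (b * c)` with the Woolf/Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a Pearson
#' chi-square p-value (no continuity correction) attached. A zero cell is an
#' error unless the Haldane-Anscombe 0.5 correction is switched on, in which
#' case the method tag records it.
#'
#' @param table A [contingency_2x2()] (or any 2x2 matrix laid out the same
#'   way).
#' @param haldane Add 0.5 to every cell when any cell is zero (default
#'   FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `or_result`: `or`, `ci_low`, `ci_high`, `method`
#'   (`woolf_wald`, with `_haldane` appended when corrected), `chisq`, `p`.
#' @export
odds_ratio <- function(table, haldane = FALSE, conf_level = 0.95) {
  m <- unclass(as.matrix(table))
  stopifnot(all(dim(m) == c(2L, 2L)))
  method <- "woolf_wald"
  cells <- as.numeric(t(m))  # a, b, c, d
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell; odds ratio degenerate (set haldane = TRUE for the ",
           "0.5 correction)", call. = FALSE)
    }
    cells <- cells + 0.5
    method <- "woolf_wald_haldane"
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  z <- qnorm(1 - (1 - conf_level) / 2)
  selog <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  cs <- chi_square(m)
  structure(list(or = or,
                 ci_low = exp(log(or) - z * selog),
                 ci_high = exp(log(or) + z * selog),
                 method = method,
                 conf_level = conf_level,
                 chisq = cs$statistic,
                 p = cs$p),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f), chi-square %.3f, p = %.4g [%s]\n",
              x$or, 100 * x$conf_level, x$ci_low, x$ci_high, x$chisq, x$p,
              x$method))
  invisible(x)
}

#' Pearson chi-square test on a 2xk contingency table
#'
#' No continuity correction by default (Yates available behind the flag);
#' p-value from the chi-square distribution on k - 1 df. All expected counts
#' must be positive.
#'
#' @param table 2-by-k matrix of counts.
#' @param correct Apply the Yates continuity correction (2x2 only; default
#'   FALSE).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(table, correct = FALSE) {
  m <- unclass(as.matrix(table))
  if (nrow(m) != 2L || ncol(m) < 2L) {
    stop("expecting a 2 x k table", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("zero expected count; chi-square undefined", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on a design matrix
#' (intercept column included by the caller). For a single binary covariate
#' the exponentiated slope equals the sample odds ratio. Complete separation
#' is reported as an explicit error (detected as a diverging coefficient,
#' |beta| > 15), as is non-convergence.
#'
#' @param design Numeric n-by-p design matrix; no covariate may be constant
#'   (one all-ones intercept column is allowed); n > p required.
#' @param outcome Binary (0/1 or logical) vector of length n.
#' @param max_iter IRLS iteration cap (default 50).
#' @param tol Convergence tolerance on the deviance (default 1e-10).
#' @param conf_level Wald CI level (default 0.95).
#' @return List of class `logistic_fit`: `coefficients`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`, `or = exp(coefficients)`, `converged`,
#'   `iterations`.
#' @export
logistic_fit <- function(design, outcome, max_iter = 50L, tol = 1e-10,
                         conf_level = 0.95) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary",
                                       call. = FALSE)
  n <- nrow(design)
  p <- ncol(design)
  if (length(outcome) != n) stop("design/outcome length mismatch",
                                 call. = FALSE)
  if (n <= p) stop("need more observations than covariates", call. = FALSE)
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))[
      seq_len(p)]
  }
  const <- apply(design, 2L, function(col) length(unique(col)) == 1L)
  intercept_like <- const & apply(design, 2L, function(col) all(col == 1))
  if (any(const & !intercept_like) || sum(intercept_like) > 1L) {
    stop("constant covariate in design", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm.fit(design, outcome, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter))
  )
  coefs <- fit$coefficients
  if (any(is.na(coefs))) {
    stop("design is rank deficient", call. = FALSE)
  }
  if (any(abs(coefs) > 15)) {
    stop("complete separation detected (|coefficient| > 15)", call. = FALSE)
  }
  if (!fit$converged) {
    stop("IRLS did not converge in ", max_iter, " iterations (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  z <- coefs / se
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coefficients = coefs,
    se = setNames(se, names(coefs)),
    z = z,
    p = 2 * pnorm(-abs(z)),
    ci_low = coefs - zcrit * se,
    ci_high = coefs + zcrit * se,
    or = exp(coefs),
    converged = TRUE,
    iterations = fit$iter
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p,
                    or = x$or)
  cat(sprintf("Logistic fit (IRLS, %d iterations)\n", x$iterations))
  print(round(tab, 4))
  invisible(x)
}

#' Expand a 2x2 table into subject-level design and outcome
#'
#' Convenience for checking the odds-ratio/logistic equivalence: `a` exposed
#' events, `b` exposed non-events, `c` unexposed events, `d` unexposed
#' non-events.
#'
#' @param a,b,c,d Cell counts.
#' @return List with `design` (intercept + exposure indicator) and
#'   `outcome`.
#' @export
expand_2x2 <- function(a, b, c, d) {
  exposure <- c(rep(1, a + b), rep(0, c + d))
  outcome <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(design = cbind(`(Intercept)` = 1, exposure = exposure),
       outcome = outcome)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the linear regression
#' of covariate k on the remaining covariates (plus intercept). Values at or
#' above `flag_level` are flagged; perfect collinearity is reported as an
#' infinite, flagged VIF rather than an error.
#'
#' @param design Numeric design matrix with >= 2 non-intercept covariates
#'   (an all-ones intercept column is detected and excluded from the
#'   output).
#' @param flag_level Flag threshold (default 5).
#' @return data.frame with columns `covariate`, `vif`, `flagged`.
#' @export
vif <- function(design, flag_level = 5) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  intercept <- apply(design, 2L, function(col) all(col == col[1L]) &&
                       col[1L] == 1)
  covs <- design[, !intercept, drop = FALSE]
  if (ncol(covs) < 2L) stop("need >= 2 non-intercept covariates",
                            call. = FALSE)
  out <- vapply(seq_len(ncol(covs)), function(k) {
    y <- covs[, k]
    X <- cbind(1, covs[, -k, drop = FALSE])
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = colnames(covs), vif = out,
             flagged = out >= flag_level, row.names = NULL,
             stringsAsFactors = FALSE)
}
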