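#' Recompute published odds ratios from bundled cross-tabulations
#'
#' The package ships the published cross-tabulated counts (recurrence by
#' morphologic TIL dichotomization and by tumor necrosis) from the two
#' localized-ccRCC cohorts the analysis models, together with the odds
#' ratios printed for them. This helper recomputes each odds ratio with
#' [odds_ratio()] and compares it to the printed value at one unit in the
#' last printed digit (printed values may be truncated rather than
#' rounded). Failures are listed, not thrown.
#'
#' @param fixture CSV with columns `name`, `cohort`, `comparison`, `a`,
#'   `b`, `c`, `d`, `expected_or`, `digits`; defaults to the bundled table.
#' @return data.frame with the recomputed `or`, the `expected_or`, the
#'   comparison `tolerance` and a logical `pass` per row (zero rows for an
#'   empty fixture).
#' @export
validate_tables <- function(fixture = NULL) {
  if (is.null(fixture)) {
    fixture <- system.file("extdata", "cohort_crosstabs.csv",
                           package = "rccimmune")
  }
  tab <- read.csv(fixture, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(data.frame(name = character(0), or = numeric(0),
                      expected_or = numeric(0), tolerance = numeric(0),
                      pass = logical(0)))
  }
  or <- vapply(seq_len(nrow(tab)), function(i) {
    odds_ratio(contingency_2x2(tab$a[i], tab$b[i], tab$c[i], tab$d[i]))$or
  }, numeric(1))
  tol <- 10^-tab$digits
  data.frame(name = tab$name, cohort = tab$cohort,
             comparison = tab$comparison, or = or,
             expected_or = tab$expected_or, tolerance = tol,
             pass = abs(or - tab$expected_or) <= tol,
             row.names = NULL, stringsAsFactors = FALSE)
}
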