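#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every tunable of the synthetic-data module. The
#' defaults emulate the design of the discovery cohort the analysis targets:
#' a 770-probe immune panel (730 endogenous genes + 40 housekeeping genes)
#' with spiked-in positive/negative controls, and a cohort of 127 patients of
#' whom 24 recurred after nephrectomy.
#'
#' @param n_samples Number of patients to simulate.
#' @param recurrence_fraction Probability that a sample is labeled recurrent;
#'   strictly between 0 and 1.
#' @param n_endogenous Number of endogenous (biological) probes.
#' @param n_housekeeping Number of housekeeping probes.
#' @param n_pos_controls Number of spike-in positive control probes (the
#'   concentration ladder).
#' @param n_neg_controls Number of spike-in negative control probes.
#' @param genes_per_cell_type Genes assigned to each cell-type signature
#'   (the Treg signature always contains the single gene FOXP3).
#' @param n_category_specific Extra genes assigned to each response category
#'   on top of its constituent cell-type signatures, pool permitting.
#' @param library_size_sd Natural-log-scale SD of the per-sample library
#'   scaling factor.
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param effect_map Named list mapping signature name to the log2
#'   fold-change planted on that signature's genes in recurrent samples.
#' @param latent_tcell_sd SD of the per-sample latent T-cell infiltration
#'   level (log2 scale) applied to T-cell signature genes and driving the
#'   morphologic TIL foci link.
#' @param til_link_strength Multiplier linking the latent T-cell level to the
#'   log mean of per-slide TIL foci counts; 0 decouples them.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal baseline expression
#'   of unannotated endogenous genes.
#' @param signature_log2_mean Log2 baseline mean for signature-member genes
#'   (marker genes on curated panels are reliably detected, so they sit
#'   above background).
#' @param housekeeping_log2_mean,housekeeping_log2_sd Log2-normal baseline of
#'   housekeeping genes.
#' @param neg_control_mean Poisson mean of negative-control (background)
#'   counts.
#' @param pos_control_scale Counts per ladder unit for positive controls;
#'   the default puts the lowest ladder rung (0.125 units) at ~50 counts,
#'   matching the scale of real spike-in reads and keeping the geometric
#'   mean well-defined.
#' @param foci_base_rate Baseline Poisson mean of per-slide TIL foci counts.
#' @param seed Integer seed; fully determines the simulated cohort.
#'
#' @return A validated list of class `simulation_config`.
#' @seealso [build_panel()], [simulate_cohort()]
#' @export
simulation_config <- function(n_samples = 127L,
                              recurrence_fraction = 24 / 127,
                              n_endogenous = 730L,
                              n_housekeeping = 40L,
                              n_pos_controls = 6L,
                              n_neg_controls = 8L,
                              genes_per_cell_type = 10L,
                              n_category_specific = 30L,
                              library_size_sd = 0.15,
                              dispersion = 0.1,
                              effect_map = list(),
                              latent_tcell_sd = 1,
                              til_link_strength = 1,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5,
                              signature_log2_mean = 8,
                              housekeeping_log2_mean = 9,
                              housekeeping_log2_sd = 0.5,
                              neg_control_mean = 8,
                              pos_control_scale = 400,
                              foci_base_rate = 1.5,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    recurrence_fraction = recurrence_fraction,
    n_endogenous = as.integer(n_endogenous),
    n_housekeeping = as.integer(n_housekeeping),
    n_pos_controls = as.integer(n_pos_controls),
    n_neg_controls = as.integer(n_neg_controls),
    genes_per_cell_type = as.integer(genes_per_cell_type),
    n_category_specific = as.integer(n_category_specific),
    library_size_sd = library_size_sd,
    dispersion = dispersion,
    effect_map = effect_map,
    latent_tcell_sd = latent_tcell_sd,
    til_link_strength = til_link_strength,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    signature_log2_mean = signature_log2_mean,
    housekeeping_log2_mean = housekeeping_log2_mean,
    housekeeping_log2_sd = housekeeping_log2_sd,
    neg_control_mean = neg_control_mean,
    pos_control_scale = pos_control_scale,
    foci_base_rate = foci_base_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_samples", "n_endogenous", "n_housekeeping",
              "n_pos_controls", "n_neg_controls", "genes_per_cell_type")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("'", nm, "' must be a single positive integer", call. = FALSE)
    }
  }
  if (cfg$n_category_specific < 0L) {
    stop("'n_category_specific' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(cfg$recurrence_fraction) ||
      cfg$recurrence_fraction <= 0 || cfg$recurrence_fraction >= 1) {
    stop("'recurrence_fraction' must lie strictly between 0 and 1",
         call. = FALSE)
  }
  for (nm in c("library_size_sd", "dispersion", "latent_tcell_sd")) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (cfg$neg_control_mean <= 0 || cfg$pos_control_scale <= 0 ||
      cfg$foci_base_rate <= 0) {
    stop("control and foci rates must be positive", call. = FALSE)
  }
  if (!is.list(cfg$effect_map) ||
      (length(cfg$effect_map) > 0 && is.null(names(cfg$effect_map)))) {
    stop("'effect_map' must be a named list of log2 fold-changes",
         call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic ccRCC cohort configuration\n")
  cat(sprintf("  %d samples, recurrence fraction %.3f, seed %d\n",
              x$n_samples, x$recurrence_fraction, x$seed))
  cat(sprintf("  panel: %d endogenous + %d housekeeping + %d pos + %d neg probes\n",
              x$n_endogenous, x$n_housekeeping,
              x$n_pos_controls, x$n_neg_controls))
  if (length(x$effect_map)) {
    cat("  planted effects:",
        paste(sprintf("%s=%+.2f", names(x$effect_map),
                      unlist(x$effect_map)), collapse = ", "), "\n")
  } else {
    cat("  planted effects: none (null cohort)\n")
  }
  invisible(x)
}
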