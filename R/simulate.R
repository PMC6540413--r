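#' Simulate raw counts for a synthetic cohort
#'
#' Draws a probe-by-sample count matrix with the statistical structure the
#' downstream analysis assumes. Endogenous and housekeeping counts are
#' negative-binomial with mean
#' `library_factor_j * 2^(baseline_g + log2fc_g * recurrent_j + latent_j * [g in T-cell])`;
#' positive controls follow a fixed 4-fold geometric concentration ladder
#' (128, 32, 8, 2, 0.5, 0.125 units) scaled by the library factor; negative
#' controls are low-mean Poisson background independent of biology.
#' Recurrence labels are Bernoulli(`recurrence_fraction`); if a draw leaves
#' either group empty the first sample's label is flipped so two-group
#' statistics stay defined.
#'
#' Randomness is consumed in a fixed documented order from
#' `set.seed(config$seed)`; [simulate_foci()] uses the offset stream
#' `config$seed + 101`.
#'
#' @param panel An [build_panel()] output.
#' @param config The [simulation_config()] used to build the panel.
#' @return A list of class `simulated_cohort`: `raw` ([rcc_set()]),
#'   `annotation` (data.frame with `sample_id`, `recurrent`, `grade`,
#'   `necrosis`, `stage`), `truth` (per-gene planted `log2fc`, per-sample
#'   `latent_tcell` and `library_factors`, `baseline_log2`), and the
#'   panel's signature registry.
#' @export
simulate_counts <- function(panel, config) {
  stopifnot(inherits(panel, "immune_panel"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  probes <- panel$probes
  endo <- probes$Name[probes$CodeClass == "Endogenous"]
  hk <- probes$Name[probes$CodeClass == "Housekeeping"]
  n <- config$n_samples

  # 1) baselines: signature members sit above background by design
  sig_genes <- unique(unlist(lapply(panel$signatures, `[[`, "genes")))
  mu0 <- rnorm(length(endo), config$baseline_log2_mean, config$baseline_log2_sd)
  in_sig <- endo %in% sig_genes
  mu0[in_sig] <- rnorm(sum(in_sig), config$signature_log2_mean,
                       config$baseline_log2_sd)
  names(mu0) <- endo
  hk0 <- rnorm(length(hk), config$housekeeping_log2_mean,
               config$housekeeping_log2_sd)
  names(hk0) <- hk

  # 2) per-sample latent structure
  lib <- exp(rnorm(n, 0, config$library_size_sd))
  rec <- rbinom(n, 1L, config$recurrence_fraction) == 1L
  if (all(rec) || !any(rec)) rec[1L] <- !rec[1L]
  latent <- rnorm(n, 0, config$latent_tcell_sd)

  # 3) planted group effects (additive in log2 across affected signatures)
  log2fc <- setNames(numeric(length(endo)), endo)
  for (sig_name in names(config$effect_map)) {
    sig <- panel$signatures[[sig_name]]
    if (is.null(sig)) {
      stop("effect_map names unknown signature '", sig_name, "'",
           call. = FALSE)
    }
    log2fc[sig$genes] <- log2fc[sig$genes] +
      as.numeric(config$effect_map[[sig_name]])
  }
  tcell <- endo %in% panel$signatures[["T-cell"]]$genes

  # 4) counts
  log2mu <- outer(mu0, rep(1, n)) +
    outer(log2fc, as.numeric(rec)) +
    outer(as.numeric(tcell), latent)
  mu_endo <- sweep(2^log2mu, 2L, lib, `*`)
  mu_hk <- sweep(2^outer(hk0, rep(1, n)), 2L, lib, `*`)
  draw <- function(mu) {
    m <- if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      rpois(length(mu), mu)
    }
    matrix(m, nrow = nrow(mu), dimnames = dimnames(mu))
  }
  cnt_endo <- draw(mu_endo)
  cnt_hk <- draw(mu_hk)
  ladder <- 128 * 4^-(seq_len(config$n_pos_controls) - 1L)
  mu_pos <- outer(ladder * config$pos_control_scale, lib)
  cnt_pos <- matrix(rpois(length(mu_pos), mu_pos), nrow = nrow(mu_pos))
  cnt_neg <- matrix(rpois(config$n_neg_controls * n, config$neg_control_mean),
                    nrow = config$n_neg_controls)

  counts <- rbind(cnt_endo, cnt_hk, cnt_pos, cnt_neg)
  rownames(counts) <- probes$Name
  colnames(counts) <- sprintf("SAMPLE%03d", seq_len(n))
  raw <- rcc_set(counts, probes$CodeClass)

  # 5) clinicopathologic covariates with mild planted recurrence links
  grade <- sample(1:4, n, replace = TRUE, prob = c(0.08, 0.20, 0.45, 0.27))
  necrosis <- rbinom(n, 1L, plogis(qlogis(0.22) + 1.2 * rec)) == 1L
  stage_high <- rbinom(n, 1L, plogis(qlogis(0.45) + 1.0 * rec)) == 1L

  annotation <- data.frame(
    sample_id = colnames(counts),
    recurrent = rec,
    grade = grade,
    necrosis = necrosis,
    stage = ifelse(stage_high, ">T1", "T1"),
    stringsAsFactors = FALSE
  )
  truth <- list(log2fc = log2fc, latent_tcell = setNames(latent,
                                                         colnames(counts)),
                library_factors = setNames(lib, colnames(counts)),
                baseline_log2 = c(mu0, hk0))
  structure(list(raw = raw, annotation = annotation, truth = truth,
                 signatures = panel$signatures, config = config),
            class = "simulated_cohort")
}

#' Simulate per-slide morphologic TIL foci counts
#'
#' Each patient contributes 1-10 H&E slides (uniform); per-slide focus counts
#' are Poisson with mean `foci_base_rate * exp(til_link_strength * latent_tcell)`,
#' so `til_link_strength = 0` decouples morphology from expression while
#' large values make the derived TIL score track the T-cell signature.
#'
#' @param truth Either a `simulated_cohort` or its `truth` element (needs
#'   `latent_tcell`).
#' @param config The [simulation_config()].
#' @return Named list (one element per sample) of integer per-slide foci
#'   counts.
#' @export
simulate_foci <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(truth, "simulated_cohort")) truth <- truth$truth
  latent <- truth$latent_tcell
  if (is.null(latent)) stop("truth lacks latent T-cell levels", call. = FALSE)
  set.seed(config$seed + 101L)
  n <- length(latent)
  n_slides <- sample.int(10L, n, replace = TRUE)
  lambda <- config$foci_base_rate * exp(config$til_link_strength * latent)
  foci <- lapply(seq_len(n), function(i) rpois(n_slides[i], lambda[i]))
  names(foci) <- names(latent)
  foci
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [build_panel()], [simulate_counts()] and
#' [simulate_foci()]; the foci lists and the derived morphologic TIL score
#' (max foci over slides, capped at 4) are appended to the annotation.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort` whose `annotation` gains list-column `foci`
#'   and integer column `til_score`.
#' @export
simulate_cohort <- function(config) {
  panel <- build_panel(config)
  cohort <- simulate_counts(panel, config)
  foci <- simulate_foci(cohort, config)
  cohort$annotation$foci <- I(unname(foci))
  cohort$annotation$til_score <- vapply(foci, aggregate_til_score, integer(1))
  cohort
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated ccRCC cohort: %d samples (%d recurrent), %d probes\n",
              ncol(x$raw$counts), sum(x$annotation$recurrent),
              nrow(x$raw$counts)))
  invisible(x)
}
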