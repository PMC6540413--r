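#' Configuration for the end-to-end pipeline
#'
#' @param mode `"simulate"` (generate a synthetic cohort), `"rcc_dir"` (load
#'   RCC-dialect files) or `"tsv"` (load a combined count TSV). Load modes
#'   need `annotation` and `gmt` paths, and `rcc_dir`/`counts` respectively.
#' @param sim A [simulation_config()] used in simulate mode; its seed is
#'   overridden by `seed`.
#' @param rcc_dir,counts,annotation,gmt Input paths for the load modes.
#' @param platform `"nanostring_log2"` or `"fpkm_log2"`, controls the
#'   Teff/Treg ratio rule.
#' @param fc_threshold,fdr_threshold DEG reporting thresholds (1.5, 0.3).
#' @param exact_cutoff Wilcoxon exact-test cutoff (combined n; default 12).
#' @param vif_flag_level VIF flag threshold (default 5).
#' @param dichotomization TIL cut-off scheme, `"cut2"` or `"cut3"`.
#' @param n_clusters Flat sample clusters to cut (default 2).
#' @param linkage Clustering linkage (default `"complete"`).
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed controlling every random stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "rcc_dir", "tsv"),
                            sim = simulation_config(),
                            rcc_dir = NULL, counts = NULL,
                            annotation = NULL, gmt = NULL,
                            platform = c("nanostring_log2", "fpkm_log2"),
                            fc_threshold = 1.5, fdr_threshold = 0.3,
                            exact_cutoff = 12L, vif_flag_level = 5,
                            dichotomization = c("cut2", "cut3"),
                            n_clusters = 2L, linkage = "complete",
                            out_dir = tempfile("rccimmune_run_"),
                            seed = 1L) {
  mode <- match.arg(mode)
  platform <- match.arg(platform)
  dichotomization <- match.arg(dichotomization)
  if (fc_threshold <= 0 || fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("thresholds out of range", call. = FALSE)
  }
  if (mode != "simulate") {
    need <- if (mode == "rcc_dir") list(rcc_dir, annotation, gmt)
            else list(counts, annotation, gmt)
    missing <- vapply(need, function(pth) {
      is.null(pth) || !file.exists(pth)
    }, logical(1))
    if (any(missing)) {
      stop(mode, " mode needs existing ",
           if (mode == "rcc_dir") "'rcc_dir'" else "'counts'",
           ", 'annotation' and 'gmt' paths", call. = FALSE)
    }
  }
  structure(list(mode = mode, sim = sim, rcc_dir = rcc_dir, counts = counts,
                 annotation = annotation, gmt = gmt, platform = platform,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 exact_cutoff = as.integer(exact_cutoff),
                 vif_flag_level = vif_flag_level,
                 dichotomization = dichotomization,
                 n_clusters = as.integer(n_clusters), linkage = linkage,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys override [pipeline_config()] defaults; a `sim` mapping
#' overrides [simulation_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  sim <- if (is.null(sim_args)) simulation_config() else {
    do.call(simulation_config, sim_args)
  }
  do.call(pipeline_config, c(list(sim = sim), raw))
}

# deterministic hash of a config (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulate or load), background
#' flooring, positive-control normalization, log2 + quantile normalization,
#' signature scoring (cell types, response categories, Teff, Treg and the
#' Teff/Treg ratio), Z standardization with per-signature recurrence
#' association (mean-Z difference + Wilcoxon), moderated-t DEG with BH FDR
#' and fold-change filtering, gene-wise Z + overlap-excluded
#' response-category clustering, and the morphologic TIL statistics (score
#' aggregation, dichotomization, odds ratio, chi-square, logistic
#' regression, VIF). All artifacts are written to `config$out_dir` as
#' TSV/CSV/JSON with provenance headers; a failing stage aborts with the
#' stage name and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return The run report (also written as `report.json`): provenance
#'   (config hash, seed, stage order, timings), artifact paths, and
#'   headline summaries (per-signature association, DEG reported count,
#'   TIL odds ratio).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  timings <- numeric(0)
  say <- function(...) if (!quiet) message("[rccimmune] ", ...)
  run_stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    timings <<- c(timings, proc.time()[["elapsed"]] - t0)
    res
  }

  acquired <- run_stage("acquire", {
    if (config$mode == "simulate") {
      sim <- config$sim
      sim$seed <- config$seed
      cohort <- simulate_cohort(sim)
      list(raw = cohort$raw, annotation = cohort$annotation,
           registry = cohort$signatures, truth = cohort$truth)
    } else {
      raw <- if (config$mode == "rcc_dir") read_rcc_files(config$rcc_dir)
             else read_counts_tsv(config$counts)
      ann <- read_annotation_csv(config$annotation)
      if (!all(ann$sample_id %in% raw$samples)) {
        stop("annotation sample IDs missing from count matrix")
      }
      raw$counts <- raw$counts[, ann$sample_id, drop = FALSE]
      raw$samples <- ann$sample_id
      if (is.null(ann$til_score) && !is.null(ann$foci)) {
        ann$til_score <- vapply(ann$foci, aggregate_til_score, integer(1))
      }
      list(raw = raw, annotation = ann, registry = read_gmt(config$gmt),
           truth = NULL)
    }
  })
  raw <- acquired$raw
  ann <- acquired$annotation
  registry <- acquired$registry
  rec <- as.logical(ann$recurrent)

  floored <- run_stage("background_floor", background_floor(raw))
  posnorm <- run_stage("positive_control_normalize",
                       positive_control_normalize(floored))
  norm <- run_stage("log2_quantile_normalize",
                    log2_quantile_normalize(posnorm))

  scoring <- run_stage("signature_scores", {
    scores <- score_signatures(norm, registry,
                               kinds = c("cell_type", "response_category"))
    teff_sig <- registry[signature_kinds(registry) == "teff"]
    teff <- if (length(teff_sig)) {
      teff_score(norm, teff_sig[[1L]])
    } else {
      NULL
    }
    treg <- if ("Treg" %in% names(registry)) {
      score_signature(norm, registry[["Treg"]])
    } else {
      NULL
    }
    ratio <- if (!is.null(teff) && !is.null(treg)) {
      teff_treg_ratio(teff, treg, config$platform)
    } else {
      NULL
    }
    list(scores = scores, teff = teff, treg = treg, ratio = ratio)
  })

  assoc <- run_stage("association", {
    res <- signature_association(scoring$scores, rec, config$exact_cutoff)
    if (!is.null(scoring$ratio)) {
      ratio_test <- wilcoxon_rank_sum(scoring$ratio[rec],
                                      scoring$ratio[!rec], "less",
                                      config$exact_cutoff)
      attr(res, "teff_treg") <- list(
        p_one_sided_less = ratio_test$p,
        p_two_sided = wilcoxon_rank_sum(scoring$ratio[rec],
                                        scoring$ratio[!rec], "two_sided",
                                        config$exact_cutoff)$p,
        platform = config$platform)
    }
    res
  })

  deg <- run_stage("deg", deg_table(norm, rec, config$fc_threshold,
                                    config$fdr_threshold))

  clust <- run_stage("clustering", {
    genes <- category_gene_set(registry)
    genes <- intersect(genes, rownames(norm))
    sub <- norm[genes, , drop = FALSE]
    keep <- apply(sub, 1L, sd) > 0
    if (!all(keep)) {
      warning(sum(!keep), " constant gene(s) dropped before clustering",
              call. = FALSE)
    }
    hierarchical_cluster(gene_zscore(sub[keep, , drop = FALSE]),
                         n_clusters = config$n_clusters,
                         linkage = config$linkage)
  })

  morph <- run_stage("morphology", {
    if (is.null(ann$til_score)) {
      warning("no TIL scores in annotation; morphology stage skipped",
              call. = FALSE)
      NULL
    } else {
      til_high <- dichotomize(ann$til_score, config$dichotomization) == "high"
      tab <- contingency_2x2(sum(til_high & rec), sum(til_high & !rec),
                             sum(!til_high & rec), sum(!til_high & !rec))
      or <- tryCatch(odds_ratio(tab),
                     error = function(e) odds_ratio(tab, haldane = TRUE))
      lf <- tryCatch(
        logistic_fit(cbind(`(Intercept)` = 1, til_high = as.numeric(til_high)),
                     as.numeric(rec)),
        error = function(e) conditionMessage(e))
      design <- cbind(
        til_high = as.numeric(til_high),
        necrosis = as.numeric(ann$necrosis),
        grade_high = as.numeric(ann$grade >= 3),
        stage_high = as.numeric(ann$stage != "T1")
      )
      vifs <- tryCatch(vif(cbind(1, design), config$vif_flag_level),
                       error = function(e) conditionMessage(e))
      list(table = tab, odds_ratio = or, logistic = lf, vif = vifs,
           scheme = config$dichotomization)
    }
  })

  outputs <- run_stage("write_artifacts", {
    paths <- list(
      normalized = file.path(config$out_dir, "normalized_log2.tsv"),
      scores = file.path(config$out_dir, "signature_scores.tsv"),
      association = file.path(config$out_dir, "signature_association.tsv"),
      deg = file.path(config$out_dir, "deg.tsv"),
      cluster = file.path(config$out_dir, "cluster.json"),
      annotation = file.path(config$out_dir, "annotation.csv"),
      morphology = file.path(config$out_dir, "morphology.json"),
      report = file.path(config$out_dir, "report.json")
    )
    write_matrix_tsv(norm, paths$normalized)
    write_matrix_tsv(t(scoring$scores), paths$scores,
                     provenance = "log2-mean signature scores (samples as columns)")
    write.table(assoc, paths$association, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(deg, paths$deg, sep = "\t", quote = FALSE, row.names = FALSE)
    write_cluster_json(clust, paths$cluster)
    write_annotation_csv(ann, paths$annotation)
    if (!is.null(morph)) {
      jsonlite::write_json(list(
        scheme = morph$scheme,
        table = as.vector(morph$table),
        odds_ratio = morph$odds_ratio[c("or", "ci_low", "ci_high", "method",
                                        "chisq", "p")],
        vif = morph$vif
      ), paths$morphology, auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    paths
  })

  report <- list(
    package = "rccimmune",
    version = as.character(utils::packageVersion("rccimmune")),
    seed = config$seed,
    config_hash = config_hash(config),
    mode = config$mode,
    platform = config$platform,
    stages = stages,
    timings_sec = setNames(round(timings, 3), stages),
    outputs = outputs,
    summaries = list(
      n_samples = ncol(raw$counts),
      n_recurrent = sum(rec),
      n_signatures = ncol(scoring$scores),
      association = assoc,
      teff_treg = attr(assoc, "teff_treg"),
      deg_reported = sum(deg$reported),
      morphology_or = if (!is.null(morph)) morph$odds_ratio$or else NA_real_
    )
  )
  jsonlite::write_json(report, outputs$report, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  say("done: ", length(stages), " stages, outputs in ", config$out_dir)
  invisible(report)
}
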