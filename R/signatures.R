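#' Construct a gene signature
#'
#' @param name Signature name (e.g. "T-cell", "Adaptive", "Teff").
#' @param genes Character vector of member gene symbols; must be non-empty.
#' @param kind One of `"cell_type"`, `"response_category"`, `"teff"`.
#' @return A list of class `gene_signature`.
#' @export
gene_signature <- function(name,
                           genes,
                           kind = c("cell_type", "response_category", "teff")) {
  kind <- match.arg(kind)
  genes <- unique(as.character(genes))
  if (length(name) != 1L || !nzchar(name)) {
    stop("signature name must be a non-empty string", call. = FALSE)
  }
  if (length(genes) == 0L) {
    stop("signature '", name, "' has an empty gene set", call. = FALSE)
  }
  structure(list(name = name, genes = genes, kind = kind),
            class = "gene_signature")
}

#' Build a registry of gene signatures
#'
#' @param signatures A list of [gene_signature()] objects with unique names.
#'   Genes may belong to several signatures; the overlap-exclusion rule used
#'   before clustering depends on it.
#' @return A named list of class `signature_registry`.
#' @export
signature_registry <- function(signatures) {
  stopifnot(is.list(signatures))
  ok <- vapply(signatures, inherits, logical(1), "gene_signature")
  if (!all(ok)) stop("all elements must be gene_signature objects",
                     call. = FALSE)
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate signature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(signatures) <- nms
  structure(signatures, class = "signature_registry")
}

#' @export
print.signature_registry <- function(x, ...) {
  cat(sprintf("Signature registry: %d signatures, %d distinct genes\n",
              length(x),
              length(unique(unlist(lapply(x, `[[`, "genes"))))))
  invisible(x)
}

#' Kinds of the signatures in a registry
#' @param registry A [signature_registry()].
#' @return Named character vector of kinds.
#' @export
signature_kinds <- function(registry) {
  vapply(registry, `[[`, character(1), "kind")
}

#' Score a gene signature on a log2 expression matrix
#'
#' The signature score of a sample is the arithmetic mean of the
#' log2-normalized expression values of the signature genes present in the
#' matrix (the "log2 mean" score). For a singleton signature — the Treg
#' signature holds only FOXP3 on this panel — the score is simply that
#' gene's value.
#'
#' @param mat Gene-by-sample numeric matrix of log2-scale values (a
#'   [log2_quantile_normalize()] output or a log2 FPKM matrix).
#' @param sig A [gene_signature()].
#' @param min_coverage Warn when fewer than this fraction of signature genes
#'   is present in the matrix (default 0.5). Missing genes are listed in the
#'   warning.
#' @return Named numeric vector of per-sample scores with attributes
#'   `coverage` (fraction of signature genes present) and `missing_genes`.
#' @export
score_signature <- function(mat, sig, min_coverage = 0.5) {
  stopifnot(is.matrix(mat), inherits(sig, "gene_signature"))
  present <- intersect(sig$genes, rownames(mat))
  if (length(present) == 0L) {
    stop("no gene of signature '", sig$name,
         "' is present in the expression matrix", call. = FALSE)
  }
  missing <- setdiff(sig$genes, present)
  coverage <- length(present) / length(sig$genes)
  if (coverage < min_coverage) {
    warning("signature '", sig$name, "' coverage ",
            sprintf("%.2f", coverage), "; missing: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  score <- colMeans(mat[present, , drop = FALSE])
  attr(score, "coverage") <- coverage
  attr(score, "missing_genes") <- missing
  score
}

#' Score every signature in a registry
#'
#' @inheritParams score_signature
#' @param registry A [signature_registry()].
#' @param kinds Restrict to signatures of these kinds (default: all).
#' @return Samples-by-signatures numeric matrix with attributes `coverage`
#'   (named vector) and `scale` (`"log2"`).
#' @export
score_signatures <- function(mat, registry, kinds = NULL, min_coverage = 0.5) {
  stopifnot(inherits(registry, "signature_registry"))
  if (!is.null(kinds)) {
    registry <- registry[signature_kinds(registry) %in% kinds]
    class(registry) <- "signature_registry"
  }
  if (length(registry) == 0L) stop("no signatures to score", call. = FALSE)
  scores <- vapply(registry, function(sig) {
    as.numeric(score_signature(mat, sig, min_coverage = min_coverage))
  }, numeric(ncol(mat)))
  if (ncol(mat) == 1L) scores <- matrix(scores, nrow = 1L,
                                        dimnames = list(NULL, names(registry)))
  rownames(scores) <- colnames(mat)
  attr(scores, "coverage") <- vapply(registry, function(sig) {
    length(intersect(sig$genes, rownames(mat))) / length(sig$genes)
  }, numeric(1))
  attr(scores, "scale") <- "log2"
  scores
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of the TPM levels of the two cytolytic effector genes
#' granzyme A (GZMA) and perforin (PRF1), each offset by 0.01:
#' `sqrt((GZMA + 0.01) * (PRF1 + 0.01))`.
#'
#' @param tpm Gene-by-sample matrix in TPM units (unit attribute, when
#'   present, must be `"TPM"`); rows `GZMA` and `PRF1` are required.
#' @param offset Pseudo-count added to each gene (default 0.01).
#' @return Named numeric vector of per-sample CYT scores.
#' @export
cyt_score <- function(tpm, offset = 0.01) {
  stopifnot(is.matrix(tpm))
  unit <- attr(tpm, "unit")
  if (!is.null(unit) && unit != "TPM") {
    stop("cyt_score expects TPM values, got unit '", unit, "'", call. = FALSE)
  }
  need <- c("GZMA", "PRF1")
  miss <- setdiff(need, rownames(tpm))
  if (length(miss)) {
    stop("cyt_score requires rows ", paste(miss, collapse = " and "),
         call. = FALSE)
  }
  sqrt((tpm["GZMA", ] + offset) * (tpm["PRF1", ] + offset))
}

#' Effector T cell (Teff) score
#'
#' Mean log2-normalized expression of the genes in a user-supplied Teff
#' signature; identical contract to [score_signature()].
#'
#' @inheritParams score_signature
#' @param teff_sig A [gene_signature()] of kind `"teff"` (other kinds are
#'   accepted but flagged with a warning).
#' @return Per-sample Teff scores.
#' @export
teff_score <- function(mat, teff_sig, min_coverage = 0.5) {
  if (teff_sig$kind != "teff") {
    warning("signature '", teff_sig$name, "' has kind '", teff_sig$kind,
            "', expected 'teff'", call. = FALSE)
  }
  score_signature(mat, teff_sig, min_coverage = min_coverage)
}

#' Teff/Treg ratio
#'
#' Ratio of the effector-T-cell score to the regulatory-T-cell (FOXP3)
#' score. On the NanoString platform the log2-scale scores are divided
#' directly (`platform = "nanostring_log2"`); on the RNA-seq platform the
#' scores are anti-logged first, so the ratio is `2^teff / 2^treg`
#' (`platform = "fpkm_log2"`).
#'
#' @param teff,treg Per-sample log2-scale scores, equal length.
#' @param platform `"nanostring_log2"` or `"fpkm_log2"`.
#' @return Numeric vector of per-sample ratios with attribute `platform`.
#'   Under `nanostring_log2` a zero Treg score yields `NA` with a warning.
#' @export
teff_treg_ratio <- function(teff, treg,
                            platform = c("nanostring_log2", "fpkm_log2")) {
  platform <- match.arg(platform)
  stopifnot(length(teff) == length(treg))
  if (platform == "nanostring_log2") {
    zero <- !is.na(treg) & treg == 0
    if (any(zero)) {
      warning(sum(zero), " sample(s) with Treg score 0; ratio set to NA",
              call. = FALSE)
    }
    ratio <- ifelse(zero, NA_real_, teff / treg)
  } else {
    ratio <- 2^(teff - treg)
  }
  attr(ratio, "platform") <- platform
  ratio
}

#' Standardize signature scores to Z scores
#'
#' Each signature column is centered by its mean and scaled by its sample SD
#' across samples, so group comparisons are on a common scale.
#'
#' @param table Samples-by-signatures score matrix with at least 2 rows.
#' @return Matrix of the same shape; every column has mean 0 and SD 1.
#' @export
standardize_scores <- function(table) {
  stopifnot(is.matrix(table))
  if (nrow(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(table, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance signature(s): ",
         paste(colnames(table)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(table, center = TRUE, scale = sds)[, , drop = FALSE]
}
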