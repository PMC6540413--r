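#' Gene-wise Z standardization of an expression matrix
#'
#' Each gene (row) is centered by its mean and scaled by its sample SD
#' across samples — the transformation applied before clustering the
#' response-category genes.
#'
#' @param mat Gene-by-sample numeric matrix, >= 2 columns.
#' @return Matrix of the same shape with row means 0 and row SDs 1.
#' @export
gene_zscore <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(mat, 1L, sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ",
         paste(utils::head(rownames(mat)[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  (mat - rowMeans(mat)) / sds
}

#' Response-category gene set for clustering
#'
#' Union of the response-category gene sets with every gene occurring in two
#' or more categories excluded, so that each clustered gene represents a
#' single immune response category.
#'
#' @param registry A [signature_registry()] (the signatures of kind
#'   `response_category` are used) or a plain named list of character gene
#'   vectors, one per category.
#' @return Character vector of category-exclusive genes, ordered by first
#'   appearance. Empty result is an error.
#' @export
category_gene_set <- function(registry) {
  sets <- if (inherits(registry, "signature_registry")) {
    keep <- signature_kinds(registry) == "response_category"
    lapply(registry[keep], `[[`, "genes")
  } else {
    lapply(registry, as.character)
  }
  if (length(sets) < 2L) {
    stop("need >= 2 response-category gene sets", call. = FALSE)
  }
  genes <- unlist(lapply(sets, unique), use.names = FALSE)
  counts <- table(genes)
  keep <- names(counts)[counts == 1L]
  out <- genes[genes %in% keep]
  out <- out[!duplicated(out)]
  if (length(out) == 0L) {
    stop("all category genes are shared between categories; nothing left ",
         "to cluster", call. = FALSE)
  }
  out
}

#' Agglomerative hierarchical clustering of genes and samples
#'
#' Clusters the rows (genes) and columns (samples) of a gene-wise
#' standardized matrix with Euclidean distance and complete linkage by
#' default. The agglomeration is deterministic given the input order (tied
#' merges resolve to the lowest-index pair, the behavior of the stats
#' agglomeration).
#'
#' @param zmat Numeric matrix (typically [gene_zscore()] output restricted
#'   to [category_gene_set()]), all finite, >= 2 rows and >= 2 columns.
#' @param n_clusters Number of flat sample clusters to cut (default 2).
#' @param linkage Linkage criterion for [stats::hclust()] (default
#'   `"complete"`).
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @return List of class `cluster_result`: `gene_order` and `sample_order`
#'   (permutations, as plotted), `gene_heights`/`sample_heights`
#'   (non-decreasing merge heights), `gene_merge`/`sample_merge`,
#'   `sample_clusters` (flat labels), and the two `hclust` trees.
#' @export
hierarchical_cluster <- function(zmat, n_clusters = 2L, linkage = "complete",
                                 distance = "euclidean") {
  stopifnot(is.matrix(zmat))
  if (!all(is.finite(zmat))) stop("non-finite values in matrix",
                                  call. = FALSE)
  if (nrow(zmat) < 2L || ncol(zmat) < 2L) {
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  }
  gene_hc <- hclust(dist(zmat, method = distance), method = linkage)
  sample_hc <- hclust(dist(t(zmat), method = distance), method = linkage)
  structure(list(
    gene_order = gene_hc$order,
    sample_order = sample_hc$order,
    gene_heights = gene_hc$height,
    sample_heights = sample_hc$height,
    gene_merge = gene_hc$merge,
    sample_merge = sample_hc$merge,
    sample_clusters = cutree(sample_hc, k = min(n_clusters, ncol(zmat))),
    gene_tree = gene_hc,
    sample_tree = sample_hc,
    linkage = linkage,
    distance = distance
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Hierarchical clustering (%s linkage, %s distance): %d genes x %d samples, %d flat clusters\n",
    x$linkage, x$distance, length(x$gene_order), length(x$sample_order),
    length(unique(x$sample_clusters))))
  invisible(x)
}

#' Serialize a cluster result as JSON
#'
#' Writes the orders, heights and flat labels (everything needed to draw a
#' heatmap) — not the tree objects.
#' @param x A `cluster_result`.
#' @param path Output file.
#' @export
write_cluster_json <- function(x, path) {
  stopifnot(inherits(x, "cluster_result"))
  jsonlite::write_json(list(
    gene_order = x$gene_order,
    sample_order = x$sample_order,
    gene_heights = x$gene_heights,
    sample_heights = x$sample_heights,
    sample_clusters = as.list(x$sample_clusters),
    linkage = x$linkage,
    distance = x$distance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
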