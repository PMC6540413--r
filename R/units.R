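#' Convert gene-level counts to FPKM
#'
#' `fpkm[g, j] = counts[g, j] * 1e9 / (length_g * total_counts_j)` —
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts Gene-by-sample matrix of non-negative counts with gene
#'   rownames; column sums must be positive.
#' @param lengths Named numeric vector of gene lengths in bp (> 0); every
#'   gene in `counts` must have a length.
#' @return FPKM matrix with attributes `unit = "FPKM"` and `gene_lengths`.
#' @export
counts_to_fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames",
                                      call. = FALSE)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stop("missing gene length for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero column sum", call. = FALSE)
  fpkm <- sweep(counts / len, 2L, tot, `/`) * 1e9
  attr(fpkm, "unit") <- "FPKM"
  attr(fpkm, "gene_lengths") <- len
  fpkm
}

#' Convert FPKM to TPM
#'
#' `tpm[g, j] = fpkm[g, j] / sum_g fpkm[g, j] * 1e6`; every column sums to
#' one million.
#'
#' @param fpkm FPKM matrix (unit attribute, when present, must be `"FPKM"`).
#' @return TPM matrix with `unit = "TPM"`.
#' @export
fpkm_to_tpm <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  unit <- attr(fpkm, "unit")
  if (!is.null(unit) && unit != "FPKM") {
    stop("fpkm_to_tpm expects FPKM input, got unit '", unit, "'",
         call. = FALSE)
  }
  tot <- colSums(fpkm)
  if (any(tot <= 0)) stop("all-zero column; TPM undefined", call. = FALSE)
  tpm <- sweep(fpkm, 2L, tot, `/`) * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Log2-transform an FPKM matrix
#'
#' @param fpkm FPKM matrix.
#' @param offset Non-negative pseudo-count added before the log (default 1);
#'   must be positive when zeros are present.
#' @return Matrix of `log2(fpkm + offset)` with `unit = "log2FPKM"` and the
#'   offset recorded in attribute `log2_offset`.
#' @export
log2_fpkm <- function(fpkm, offset = 1) {
  fpkm <- as.matrix(fpkm)
  unit <- attr(fpkm, "unit")
  if (!is.null(unit) && unit != "FPKM") {
    stop("log2_fpkm expects FPKM input, got unit '", unit, "'", call. = FALSE)
  }
  if (offset < 0) stop("offset must be non-negative", call. = FALSE)
  if (offset == 0 && any(fpkm == 0)) {
    stop("zeros present with offset 0; log2 undefined", call. = FALSE)
  }
  out <- log2(fpkm + offset)
  attr(out, "unit") <- "log2FPKM"
  attr(out, "log2_offset") <- offset
  out
}
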