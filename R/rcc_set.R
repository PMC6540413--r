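#' Raw NanoString-style count container
#'
#' Bundles a probe-by-sample count matrix with the per-probe code class
#' (Endogenous / Housekeeping / Positive / Negative), in the spirit of
#' limma's expression-set lists.
#'
#' @param counts Probe-by-sample numeric matrix of non-negative counts;
#'   rownames are probe names.
#' @param code_class Character vector, one class per probe.
#' @param provenance Character vector of processing steps already applied.
#' @return A list of class `rcc_set` with elements `counts`, `probes`
#'   (data.frame `Name`, `CodeClass`), `samples`, `provenance`.
#' @export
rcc_set <- function(counts, code_class, provenance = character(0)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have probe rownames",
                                      call. = FALSE)
  if (anyDuplicated(rownames(counts))) {
    stop("probe names must be unique", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  code_class <- as.character(code_class)
  if (length(code_class) != nrow(counts)) {
    stop("code_class length must match probe count", call. = FALSE)
  }
  bad <- setdiff(unique(code_class),
                 c("Endogenous", "Housekeeping", "Positive", "Negative"))
  if (length(bad)) {
    stop("unknown code class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("SAMPLE%03d", seq_len(ncol(counts)))
  }
  structure(list(
    counts = counts,
    probes = data.frame(Name = rownames(counts), CodeClass = code_class,
                        stringsAsFactors = FALSE),
    samples = colnames(counts),
    provenance = provenance
  ), class = "rcc_set")
}

#' @export
print.rcc_set <- function(x, ...) {
  tab <- table(x$probes$CodeClass)
  cat(sprintf("rcc_set: %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  if (length(x$provenance)) {
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.rcc_set <- function(x) dim(x$counts)

# rows of a given code class
class_rows <- function(x, classes) {
  which(x$probes$CodeClass %in% classes)
}
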