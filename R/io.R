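# Readers and writers for the plain-text interchange formats used around the
# pipeline: RCC-dialect per-sample count files, combined count TSVs, GMT gene
# sets, annotation CSVs and provenance-tagged matrix TSVs.

#' Write an rcc_set as one RCC-dialect file per sample
#'
#' Each file carries `<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>`
#' and `<Code_Summary>` sections; the code summary lists
#' `CodeClass,Name,Accession,Count` rows.
#'
#' @param x An [rcc_set()] (or `simulated_cohort`, whose `raw` is used).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_rcc_files <- function(x, dir) {
  if (inherits(x, "simulated_cohort")) x <- x$raw
  stopifnot(inherits(x, "rcc_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- sprintf("SYN_%04d", seq_len(nrow(x$counts)))
  paths <- character(0)
  for (j in seq_len(ncol(x$counts))) {
    sample_id <- x$samples[j]
    path <- file.path(dir, paste0(sample_id, ".RCC"))
    lines <- c(
      "<Header>", "FileVersion,1.7", "SoftwareVersion,synthetic", "</Header>",
      "", "<Sample_Attributes>", paste0("ID,", sample_id),
      "Owner,rccimmune", "</Sample_Attributes>",
      "", "<Lane_Attributes>", paste0("ID,", j), "</Lane_Attributes>",
      "", "<Code_Summary>", "CodeClass,Name,Accession,Count",
      sprintf("%s,%s,%s,%s", x$probes$CodeClass, x$probes$Name, acc,
              format(x$counts[, j], scientific = FALSE, trim = TRUE)),
      "</Code_Summary>"
    )
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a directory (or vector) of RCC-dialect files into an rcc_set
#'
#' Tolerant of extra header keys; only the `<Code_Summary>` section is
#' interpreted. All files must share the same probe set.
#'
#' @param path Directory containing `.RCC` files, or a character vector of
#'   file paths.
#' @return An [rcc_set()]; sample names come from the Sample_Attributes ID
#'   (falling back to the file name).
#' @export
read_rcc_files <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.RCC$", full.names = TRUE,
               ignore.case = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) stop("no RCC files found", call. = FALSE)
  one <- function(f) {
    lines <- readLines(f)
    open <- grep("^<Code_Summary>", lines)
    close <- grep("^</Code_Summary>", lines)
    if (length(open) != 1L || length(close) != 1L) {
      stop("malformed RCC file (Code_Summary): ", f, call. = FALSE)
    }
    body <- lines[(open + 1L):(close - 1L)]
    tab <- read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
    sid <- sub("^ID,", "", grep("^ID,", lines[seq_len(open)], value = TRUE))
    sid <- if (length(sid)) sid[1L] else sub("\\.RCC$", "", basename(f),
                                             ignore.case = TRUE)
    list(id = sid, tab = tab)
  }
  parsed <- lapply(files, one)
  ref <- parsed[[1L]]$tab
  counts <- vapply(parsed, function(p) {
    if (!identical(p$tab$Name, ref$Name)) {
      stop("RCC files disagree on probe set", call. = FALSE)
    }
    as.numeric(p$tab$Count)
  }, numeric(nrow(ref)))
  counts <- matrix(counts, nrow = nrow(ref),
                   dimnames = list(ref$Name,
                                   vapply(parsed, `[[`, character(1), "id")))
  rcc_set(counts, ref$CodeClass)
}

#' Write a combined probe-by-sample count TSV
#'
#' Columns: `CodeClass`, `Name`, then one column per sample.
#' @param x An [rcc_set()] or `simulated_cohort`.
#' @param path Output file.
#' @export
write_counts_tsv <- function(x, path) {
  if (inherits(x, "simulated_cohort")) x <- x$raw
  stopifnot(inherits(x, "rcc_set"))
  df <- cbind(x$probes[, c("CodeClass", "Name")],
              as.data.frame(x$counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a combined count TSV written by [write_counts_tsv()]
#' @param path File path.
#' @return An [rcc_set()].
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("CodeClass", "Name") %in% names(df))) {
    stop("count TSV must carry CodeClass and Name leading columns",
         call. = FALSE)
  }
  mat <- as.matrix(df[, setdiff(names(df), c("CodeClass", "Name")),
                      drop = FALSE])
  rownames(mat) <- df$Name
  rcc_set(mat, df$CodeClass)
}

#' Write a signature registry as a GMT file
#'
#' One tab-separated line per signature: name, description (used here to
#' carry the signature kind), then the gene symbols.
#' @param registry A [signature_registry()].
#' @param path Output file.
#' @export
write_gmt <- function(registry, path) {
  stopifnot(inherits(registry, "signature_registry"))
  lines <- vapply(registry, function(sig) {
    paste(c(sig$name, sig$kind, sig$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a signature registry
#'
#' The description field is interpreted as the signature kind when it is one
#' of `cell_type` / `response_category` / `teff`; otherwise the signature
#' defaults to `cell_type`.
#' @param path GMT file path.
#' @return A [signature_registry()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", ln, call. = FALSE)
    kind <- if (parts[2L] %in% c("cell_type", "response_category", "teff")) {
      parts[2L]
    } else {
      "cell_type"
    }
    gene_signature(parts[1L], parts[-(1:2)], kind)
  })
  signature_registry(sigs)
}

#' Write the cohort annotation as CSV
#'
#' Columns `sample_id`, `recurrent`, `grade`, `necrosis`, `stage`,
#' `til_score` and `foci` (per-slide counts joined by semicolons).
#' @param annotation Annotation data.frame (as in `simulated_cohort`).
#' @param path Output file.
#' @export
write_annotation_csv <- function(annotation, path) {
  out <- annotation
  if (!is.null(out$foci)) {
    out$foci <- vapply(out$foci, paste, character(1), collapse = ";")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort annotation CSV
#' @param path File written by [write_annotation_csv()].
#' @return Annotation data.frame; the `foci` column, when present, is parsed
#'   back into integer vectors.
#' @export
read_annotation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$foci)) {
    df$foci <- I(lapply(strsplit(as.character(df$foci), ";", fixed = TRUE),
                        as.integer))
  }
  df
}

#' Write a numeric matrix as TSV with '#' provenance header lines
#' @param mat Matrix with rownames.
#' @param path Output file.
#' @param provenance Character vector written as leading `# ` lines
#'   (defaults to the matrix's provenance attribute).
#' @export
write_matrix_tsv <- function(mat, path, provenance = attr(mat, "provenance")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  df <- data.frame(feature = rownames(mat),
                   as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  )
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @param path File path.
#' @return Numeric matrix; '#' lines are returned in attribute `provenance`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  prov <- sub("^# ?", "", grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  if (length(prov)) attr(mat, "provenance") <- prov
  mat
}
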