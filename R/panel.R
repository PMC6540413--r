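#' The 24 immune cell types annotated on the immune profiling panel
#'
#' @return Character vector of the 24 cell-type signature names.
#' @export
nanostring_cell_types <- function() {
  c("aDC", "B-cell", "CD8 T-cell", "Cytotoxic cell", "DC", "Eosinophils",
    "iDC", "Macrophages", "Mast cell", "Neutrophils", "NK CD56bright cell",
    "NK CD56dim cell", "NK cell", "pDC", "T helper cell", "T-cell", "Tcm",
    "Tem", "TFH", "Tgd", "Th1 cell", "Th17 cell", "Th2 cell", "Treg")
}

#' The 4 immune response categories annotated on the panel
#' @return Character vector of category names.
#' @export
response_categories <- function() {
  c("Adaptive", "Innate", "Inflammation", "Humoral")
}

# Cell types whose gene sets seed each response category. Shared cell types
# (Neutrophils/Macrophages/... between Innate and Inflammation, B-cell
# between Adaptive and Humoral) guarantee inter-category gene overlap, as in
# the real panel annotation, so the overlap-exclusion clustering rule is
# always exercised.
category_composition <- function() {
  list(
    Adaptive = c("T-cell", "CD8 T-cell", "B-cell", "Tcm", "Tem", "TFH",
                 "Th1 cell", "Th2 cell", "Treg"),
    Innate = c("NK cell", "NK CD56bright cell", "NK CD56dim cell",
               "Neutrophils", "Macrophages", "DC", "iDC", "aDC",
               "Mast cell", "Eosinophils"),
    Inflammation = c("Neutrophils", "Macrophages", "Mast cell",
                     "Eosinophils", "Th17 cell"),
    Humoral = c("B-cell", "pDC")
  )
}

#' Build the synthetic immune panel definition
#'
#' Lays out a deterministic probe set (endogenous, housekeeping, positive and
#' negative control probes) and a signature registry mirroring the structure
#' of the nCounter immune profiling annotation: 24 cell-type signatures (the
#' Treg signature containing the single gene FOXP3), a Teff (effector T cell)
#' signature drawn from the T-cell and CD8 T-cell marker sets, and 4 immune
#' response categories (Adaptive, Innate, Inflammation, Humoral) that
#' partially overlap. GZMA and PRF1 are always present (members of the
#' Cytotoxic cell signature) so cytolytic-activity scoring is defined.
#'
#' No randomness is involved: the same configuration always yields the
#' identical panel.
#'
#' @param config A [simulation_config()].
#' @return A list of class `immune_panel` with elements `probes` (data.frame
#'   with columns `CodeClass`, `Name`, `Accession`), `signatures` (a
#'   [signature_registry()]) and `config`.
#' @export
build_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$genes_per_cell_type
  special <- c("GZMA", "PRF1", "FOXP3")
  if (config$n_endogenous < length(special)) {
    stop("panel sizing error: need at least ", length(special),
         " endogenous genes (GZMA, PRF1, FOXP3)", call. = FALSE)
  }
  pool <- sprintf("IMM%04d", seq_len(config$n_endogenous - length(special)))
  genes <- c(special, pool)

  cts <- nanostring_cell_types()
  assign <- vector("list", length(cts))
  names(assign) <- cts
  assign[["Treg"]] <- "FOXP3"
  assign[["Cytotoxic cell"]] <- utils::head(c("GZMA", "PRF1", pool), k)
  used_from_pool <- max(0L, k - 2L)
  # cytolytic markers not consumed by the Cytotoxic signature (k = 1) stay
  # assignable, so minimal panels still fit every cell type
  avail <- c(setdiff(c("GZMA", "PRF1"), assign[["Cytotoxic cell"]]),
             if (used_from_pool < length(pool)) {
               pool[seq.int(used_from_pool + 1L, length(pool))]
             } else {
               character(0)
             })
  cursor <- 1L
  for (ct in setdiff(cts, c("Treg", "Cytotoxic cell"))) {
    take <- seq.int(cursor, length.out = k)
    if (take[length(take)] > length(avail)) {
      stop("panel sizing error: ", config$n_endogenous,
           " endogenous genes cannot host ", k,
           " genes per cell-type signature", call. = FALSE)
    }
    assign[[ct]] <- avail[take]
    cursor <- cursor + k
  }

  # Teff: effector T-cell markers, overlapping the T-cell / CD8 T-cell sets
  half <- max(1L, ceiling(k / 2))
  teff_genes <- unique(c(utils::head(assign[["T-cell"]], half),
                         utils::head(assign[["CD8 T-cell"]], half)))

  # Response categories: unions of constituent cell-type sets plus (when the
  # pool allows) a block of category-specific genes.
  comp <- category_composition()
  cats <- lapply(comp, function(members) {
    unique(unlist(assign[members], use.names = FALSE))
  })
  remaining <- if (cursor - 1L < length(avail)) {
    avail[seq.int(cursor, length(avail))]
  } else {
    character(0)
  }
  m <- config$n_category_specific
  if (m > 0L && length(remaining) >= 4L * m) {
    for (i in seq_along(cats)) {
      cats[[i]] <- c(cats[[i]], remaining[seq.int((i - 1L) * m + 1L,
                                                  length.out = m)])
    }
  }

  sigs <- c(
    lapply(cts, function(ct) gene_signature(ct, assign[[ct]], "cell_type")),
    list(gene_signature("Teff", teff_genes, "teff")),
    lapply(names(cats), function(cc) {
      gene_signature(cc, cats[[cc]], "response_category")
    })
  )
  registry <- signature_registry(sigs)

  probes <- data.frame(
    CodeClass = c(rep("Endogenous", config$n_endogenous),
                  rep("Housekeeping", config$n_housekeeping),
                  rep("Positive", config$n_pos_controls),
                  rep("Negative", config$n_neg_controls)),
    Name = c(genes,
             sprintf("HK%03d", seq_len(config$n_housekeeping)),
             sprintf("POS_%s", LETTERS[seq_len(config$n_pos_controls)]),
             sprintf("NEG_%s", LETTERS[seq_len(config$n_neg_controls)])),
    stringsAsFactors = FALSE
  )
  probes$Accession <- sprintf("SYN_%04d", seq_len(nrow(probes)))

  structure(list(probes = probes, signatures = registry, config = config),
            class = "immune_panel")
}

#' @export
print.immune_panel <- function(x, ...) {
  tab <- table(x$probes$CodeClass)
  cat("Synthetic immune panel:",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      "probes\n")
  cat(sprintf("  %d signatures (%d cell types, %d response categories, Teff)\n",
              length(x$signatures),
              sum(signature_kinds(x$signatures) == "cell_type"),
              sum(signature_kinds(x$signatures) == "response_category")))
  invisible(x)
}
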