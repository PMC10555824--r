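#' Quality-control parameters
#'
#' Defaults follow common droplet scRNA-seq practice: genes kept when
#' expressed (count > 0) in at least 5 cells, cells kept when they carry at
#' least 200 UMIs and at most the stage-dependent mitochondrial fraction
#' (5% for larval, 10% for adult tissue).
#'
#' @param min_cells_per_gene keep genes expressed in at least this many cells.
#' @param min_umis_per_cell keep cells with at least this many total UMIs.
#' @param max_mito_frac remove cells whose mitochondrial UMI fraction
#'   exceeds this; overridden by `stage` when given.
#' @param mito_gene_ids character vector of mitochondrial gene IDs.
#' @param stage optional `"larva"` (5%) or `"adult"` (10%) preset for
#'   `max_mito_frac`.
#' @return a `QCParams` list.
#' @export
qc_params <- function(min_cells_per_gene = 5L,
                      min_umis_per_cell = 200L,
                      max_mito_frac = 0.10,
                      mito_gene_ids = character(),
                      stage = NULL) {
  if (!is.null(stage)) {
    stage <- match.arg(stage, c("larva", "adult"))
    max_mito_frac <- if (stage == "larva") 0.05 else 0.10
  }
  if (min_cells_per_gene < 0 || min_umis_per_cell < 0)
    stop("QC thresholds must be non-negative")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_umis_per_cell = as.integer(min_umis_per_cell),
                 max_mito_frac = max_mito_frac,
                 mito_gene_ids = mito_gene_ids),
            class = "QCParams")
}

#' Filter genes and cells of a count matrix
#'
#' Filters are applied in a fixed, documented order: (1) genes expressed
#' (count > 0) in fewer than `min_cells_per_gene` cells are removed; (2)
#' cells whose total UMIs — computed on the gene-filtered matrix — fall
#' below `min_umis_per_cell` are removed; (3) of the remaining cells, those
#' whose mitochondrial UMI fraction exceeds `max_mito_frac` are removed.
#' Attribution in the report is therefore disjoint.
#'
#' @param m a [count_matrix()].
#' @param params a [qc_params()]. Mitochondrial IDs absent from the matrix
#'   are warned about and ignored.
#' @return list with `matrix` (the filtered `CountMatrix`) and `report`
#'   (a `QCReport` with per-step removal counts).
#' @export
qc_filter <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(params, "QCParams"))
  counts <- m$counts
  genes_in <- nrow(counts)
  cells_in <- ncol(counts)

  mito <- params$mito_gene_ids
  extra <- setdiff(mito, rownames(counts))
  if (length(extra)) {
    warning(length(extra), " mitochondrial gene ID(s) not in matrix; ignored")
    mito <- intersect(mito, rownames(counts))
  }

  keep_gene <- Matrix::rowSums(counts > 0) >= params$min_cells_per_gene
  counts <- counts[keep_gene, , drop = FALSE]
  mito <- intersect(mito, rownames(counts))

  totals <- Matrix::colSums(counts)
  keep_umi <- totals >= params$min_umis_per_cell

  mito_counts <- if (length(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)
  keep_mito <- mito_frac <= params$max_mito_frac

  removed_umi <- sum(!keep_umi)
  removed_mito <- sum(keep_umi & !keep_mito)
  keep_cell <- keep_umi & keep_mito
  if (!any(keep_cell)) stop("empty matrix after QC")
  counts <- counts[, keep_cell, drop = FALSE]

  report <- structure(list(
    species = m$species,
    genes_in = genes_in,
    genes_removed_low_cells = genes_in - sum(keep_gene),
    genes_out = sum(keep_gene),
    cells_in = cells_in,
    cells_removed_low_umi = removed_umi,
    cells_removed_high_mito = removed_mito,
    cells_out = ncol(counts),
    params = unclass(params)), class = "QCReport")
  list(matrix = count_matrix(counts, species = m$species), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0(
    "QC [%s]: genes %d -> %d (%d removed, <%d cells);\n",
    "  cells %d -> %d (%d low-UMI, %d high-mito)\n"),
    x$species, x$genes_in, x$genes_out, x$genes_removed_low_cells,
    x$params$min_cells_per_gene, x$cells_in, x$cells_out,
    x$cells_removed_low_umi, x$cells_removed_high_mito))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `QCReport`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
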