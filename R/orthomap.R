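#' Collapse paralogues into orthogroup meta-genes
#'
#' Sums the raw UMI counts of all paralogues belonging to the same
#' orthogroup, giving a meta-gene x cell matrix whose row IDs are the shared
#' numeric orthogroup indices `1..n`. Collapsing happens on raw counts,
#' before any normalization, so per-cell UMI totals over orthology-assigned
#' genes are conserved exactly.
#'
#' Genes present in the matrix but absent from the orthology are dropped
#' (counted in the report); orthology genes missing from the matrix
#' contribute zero and are counted as well.
#'
#' @param m a [count_matrix()] of one species.
#' @param ortho an [ortho_map()].
#' @param side which species column of `ortho` the matrix belongs to.
#' @return a `CountMatrix` of meta-genes x cells with a `collapse_report`
#'   attribute (genes assigned / dropped / missing).
#' @export
collapse_to_metagenes <- function(m, ortho, side = c("s1", "s2")) {
  stopifnot(inherits(m, "CountMatrix"), inherits(ortho, "OrthoMap"))
  side <- match.arg(side)
  lookup <- gene_to_orthogroup(ortho, side)
  genes <- gene_ids(m)
  og <- lookup[genes]
  assigned <- !is.na(og)
  if (!any(assigned))
    stop("no overlap between matrix and orthology")
  n <- n_orthogroups(ortho)

  # indicator (orthogroups x assigned genes); one matrix product does the sum
  idx <- which(assigned)
  agg <- Matrix::sparseMatrix(i = og[idx], j = seq_along(idx), x = 1,
                              dims = c(n, length(idx)))
  collapsed <- agg %*% m$counts[idx, , drop = FALSE]
  dimnames(collapsed) <- list(as.character(seq_len(n)), cell_ids(m))

  out <- count_matrix(collapsed, species = m$species)
  attr(out, "collapse_report") <- list(
    n_genes_in = length(genes),
    n_genes_assigned = length(idx),
    n_genes_dropped = length(genes) - length(idx),
    n_orthology_genes_missing = length(lookup) - length(idx))
  out
}
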