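#' Sparse genes-by-cells UMI count matrix for one species
#'
#' Thin validated container around a `Matrix::dgCMatrix` of non-negative
#' integer UMI counts with unique gene and cell identifiers, tagged with the
#' species it belongs to.
#'
#' @param counts matrix or sparse Matrix, genes in rows, cells in columns,
#'   with complete `dimnames`.
#' @param species single string labelling the species.
#' @return an object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `species`.
#' @export
count_matrix <- function(counts, species = "s1") {
  if (!inherits(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and cell (column) names")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_c <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_c))
    stop("duplicate cell IDs: ", paste(utils::head(dup_c, 5), collapse = ", "))
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers")
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("species must be a single non-empty string")
  structure(list(counts = counts, species = species), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d genes x %d cells, %d non-zero entries\n",
              x$species, nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x a `CountMatrix`.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
cell_ids <- function(x) colnames(x$counts)

#' Bipartite orthogroup map between two species' gene sets
#'
#' Orthogroups are shared numeric meta-gene indices `1..n`; each index maps
#' to a non-empty gene set in each species and every gene belongs to at most
#' one orthogroup.
#'
#' @param genes_s1,genes_s2 lists of character vectors, one element per
#'   orthogroup, in matching order.
#' @param species length-2 character vector naming the two species.
#' @param provenance free-text origin of the map (file path or "simulated").
#' @return an `OrthoMap` object.
#' @export
ortho_map <- function(genes_s1, genes_s2, species = c("s1", "s2"),
                      provenance = "constructed") {
  if (length(genes_s1) != length(genes_s2))
    stop("genes_s1 and genes_s2 must have the same number of orthogroups")
  n <- length(genes_s1)
  if (n < 1L) stop("OrthoMap needs at least one orthogroup")
  for (side in list(genes_s1, genes_s2)) {
    if (any(lengths(side) < 1L))
      stop("every orthogroup must contain at least one gene in each species")
    all_g <- unlist(side, use.names = FALSE)
    dup <- unique(all_g[duplicated(all_g)])
    if (length(dup))
      stop("gene assigned to more than one orthogroup: ",
           paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(genes_s1 = genes_s1, genes_s2 = genes_s2,
                 species = species, provenance = provenance),
            class = "OrthoMap")
}

#' @export
print.OrthoMap <- function(x, ...) {
  sz <- lengths(x$genes_s1) * lengths(x$genes_s2)
  cat(sprintf("OrthoMap: %d orthogroups (%s vs %s), %d non-1:1 (%s)\n",
              length(x$genes_s1), x$species[1], x$species[2],
              sum(sz > 1L), x$provenance))
  invisible(x)
}

#' Number of orthogroups in an OrthoMap
#' @param ortho an `OrthoMap`.
#' @export
n_orthogroups <- function(ortho) length(ortho$genes_s1)

# gene -> orthogroup index lookup for one side
gene_to_orthogroup <- function(ortho, side = c("s1", "s2")) {
  side <- match.arg(side)
  genes <- if (side == "s1") ortho$genes_s1 else ortho$genes_s2
  idx <- rep.int(seq_along(genes), lengths(genes))
  stats::setNames(idx, unlist(genes, use.names = FALSE))
}

#' Meta-genes by cell-types specificity index matrix
#'
#' Holds s_{g,c}: the mean normalized expression of meta-gene g in cell type
#' c divided by its mean over all N cells. For every gene with non-zero
#' overall mean, sum_c (n_c/N) * s_{g,c} = 1. Genes whose overall mean is
#' zero cannot be divided and are masked instead.
#'
#' @param values numeric matrix, meta-genes x cell types.
#' @param cluster_sizes named integer vector of cells per type.
#' @param normalization_tag label of the per-cell normalization used.
#' @param masked logical vector flagging zero-overall-mean genes.
#' @return a `SpecificityMatrix` object with fields `values`,
#'   `cluster_sizes`, `N`, `normalization_tag`, `masked`.
#' @export
specificity_matrix <- function(values, cluster_sizes,
                               normalization_tag = "log1p-CP10K",
                               masked = rep(FALSE, nrow(values))) {
  if (ncol(values) != length(cluster_sizes) ||
      !identical(colnames(values), names(cluster_sizes)))
    stop("columns of values must match names of cluster_sizes")
  if (length(masked) != nrow(values))
    stop("masked must have one entry per gene")
  if (any(values[!masked, , drop = FALSE] < 0))
    stop("specificity indices must be non-negative")
  structure(list(values = values,
                 cluster_sizes = cluster_sizes,
                 N = sum(cluster_sizes),
                 normalization_tag = normalization_tag,
                 masked = masked),
            class = "SpecificityMatrix")
}

#' @export
print.SpecificityMatrix <- function(x, ...) {
  cat(sprintf(
    "SpecificityMatrix: %d meta-genes (%d masked) x %d cell types, N = %d cells [%s]\n",
    nrow(x$values), sum(x$masked), ncol(x$values), x$N, x$normalization_tag))
  invisible(x)
}

#' Cross-species homology comparison result
#'
#' @param corr species-1 types x species-2 types Pearson correlation matrix.
#' @param rbh_pairs data frame of reciprocal-best-hit pairs.
#' @param dendrogram `hclust`-compatible merge tree over the union of both
#'   species' types.
#' @param support data frame of per-internal-node BP and AU support (percent).
#' @param n_boot bootstrap replicates per scale.
#' @param gene_set_tag label of the gene set the comparison used.
#' @return a `HomologyResult` object.
#' @export
homology_result <- function(corr, rbh_pairs, dendrogram = NULL,
                            support = NULL, n_boot = 0L,
                            gene_set_tag = "all") {
  ok <- corr[is.finite(corr)]
  if (length(ok) && (min(ok) < -1 - 1e-12 || max(ok) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  structure(list(corr = corr, rbh_pairs = rbh_pairs,
                 dendrogram = dendrogram, support = support,
                 n_boot = n_boot, gene_set_tag = gene_set_tag),
            class = "HomologyResult")
}

#' @export
print.HomologyResult <- function(x, ...) {
  cat(sprintf("HomologyResult: %d x %d cell types, %d RBH pairs [gene set: %s]\n",
              nrow(x$corr), ncol(x$corr), nrow(x$rbh_pairs), x$gene_set_tag))
  if (!is.null(x$support))
    cat(sprintf("  dendrogram: %d internal nodes, n_boot = %d\n",
                nrow(x$support), x$n_boot))
  invisible(x)
}
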