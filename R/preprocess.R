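#' Library-size normalization (log1p counts-per-scale)
#'
#' Per cell, counts are scaled to `scale` total counts and log-transformed:
#' `value = log(1 + count * scale / cell_total)`. Zero stays zero, so the
#' sparsity pattern is preserved, and the transform is monotone within a
#' cell.
#'
#' @param m a [count_matrix()] (post-QC: no zero-total cells).
#' @param scale target per-cell total (default 1e4, i.e. CP10K).
#' @return a `dgCMatrix` of normalized values, same dimnames as the input.
#' @export
normalize_counts <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CountMatrix"))
  counts <- m$counts
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  out <- counts
  j <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  out@x <- log1p(counts@x * scale / totals[j])
  out
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic: the variance of normalized
#' values is z-standardized within `n_bins` equal-count bins of the gene
#' mean, and the top `k` genes by standardized variance are returned. Genes
#' with zero variance are never selected ahead of any gene with positive
#' variance.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param k number of genes to select (default 3000); clamped with a warning
#'   when fewer genes are available.
#' @param n_bins number of equal-count mean bins for standardization.
#' @return character vector of selected gene IDs, highest dispersion first.
#' @export
select_hvgs <- function(norm, k = 3000L, n_bins = 20L) {
  if (k < 1L) stop("k must be >= 1")
  n_genes <- nrow(norm)
  nc <- ncol(norm)
  rs <- Matrix::rowSums(norm)
  rs2 <- Matrix::rowSums(norm^2)
  mu <- rs / nc
  v <- pmax((rs2 - nc * mu^2) / max(nc - 1, 1), 0)

  bin <- ceiling(rank(mu, ties.method = "first") * n_bins / n_genes)
  z <- numeric(n_genes)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(v[idx])
    z[idx] <- if (length(idx) > 1L && s > 0) (v[idx] - mean(v[idx])) / s else 0
  }
  z[v == 0] <- -Inf

  if (n_genes < k) {
    warning(sprintf("only %d genes available; returning all (k = %d)",
                    n_genes, k))
    k <- n_genes
  }
  rownames(norm)[order(-z, seq_len(n_genes))][seq_len(k)]
}

#' Per-cluster mean expression
#'
#' Arithmetic mean of normalized values per gene within each annotated cell
#' type. Every cell in the matrix must carry a label; annotation rows for
#' cells absent from the matrix are ignored.
#'
#' @param norm normalized matrix ([normalize_counts()]).
#' @param ann annotation data frame with `cell_id` and `cluster_label`.
#' @return list with `means` (dense genes x cell-types matrix, columns in
#'   sorted label order) and `cluster_sizes` (named integer).
#' @export
cluster_means <- function(norm, ann) {
  lab <- ann$cluster_label[match(colnames(norm), ann$cell_id)]
  if (anyNA(lab))
    stop("unlabelled cell(s): ",
         paste(utils::head(colnames(norm)[is.na(lab)], 5), collapse = ", "))
  types <- sort(unique(lab))
  empty <- setdiff(unique(ann$cluster_label), types)
  if (length(empty))
    warning("cluster(s) with no cells in matrix dropped: ",
            paste(empty, collapse = ", "))
  ind <- Matrix::sparseMatrix(i = seq_along(lab),
                              j = match(lab, types), x = 1,
                              dims = c(length(lab), length(types)))
  sizes <- stats::setNames(as.integer(Matrix::colSums(ind)), types)
  means <- as.matrix(norm %*% ind %*% Matrix::Diagonal(x = 1 / sizes))
  dimnames(means) <- list(rownames(norm), types)
  list(means = means, cluster_sizes = sizes)
}

#' Gene specificity index
#'
#' For gene `g` and cell type `c`, `s_{g,c} = g_c / g_bar`, where `g_c` is
#' the mean normalized expression of `g` in type `c` and `g_bar` is its mean
#' across all `N` cells, computed from the cluster means as
#' `sum_c n_c * g_c / N`. A value of 1 means unenriched; values above 1 mean
#' type-enriched. Genes with zero overall mean cannot be divided and are
#' masked (values `NA`, excluded from downstream correlation).
#'
#' The `within_cluster` denominator variant divides instead by
#' `n_c * g_c / N` (summing only the cells of the type itself); it is
#' provided for comparison only.
#'
#' @param means genes x cell-types matrix of cluster means.
#' @param cluster_sizes named integer vector matching the columns of `means`.
#' @param normalization_tag label recorded in the result.
#' @param denominator `"all_cells"` (default) or `"within_cluster"`.
#' @return a [specificity_matrix()].
#' @export
specificity_index <- function(means, cluster_sizes,
                              normalization_tag = "log1p-CP10K",
                              denominator = c("all_cells", "within_cluster")) {
  denominator <- match.arg(denominator)
  if (ncol(means) != length(cluster_sizes) ||
      !identical(colnames(means), names(cluster_sizes)))
    stop("means columns and cluster_sizes do not match")
  N <- sum(cluster_sizes)
  if (denominator == "all_cells") {
    gbar <- drop(means %*% cluster_sizes) / N
    names(gbar) <- rownames(means)
    masked <- gbar == 0
    s <- means / gbar
  } else {
    den <- sweep(means, 2, cluster_sizes / N, `*`)
    masked <- Matrix::rowSums(means) == 0
    s <- ifelse(den > 0, means / den, 0)
  }
  s[masked, ] <- NA_real_
  specificity_matrix(s, cluster_sizes,
                     normalization_tag =
                       paste0(normalization_tag, "/", denominator),
                     masked = masked)
}

#' Normalize, filter and summarize one species into specificity indices
#'
#' Convenience chain: [normalize_counts()], optional gene restriction
#' (explicit `gene_subset` or top-`k_hvg` highly variable genes),
#' [cluster_means()], [specificity_index()]. Gene filtering precedes
#' averaging.
#'
#' @param m a (typically meta-gene) [count_matrix()], post-QC.
#' @param ann annotation data frame (`cell_id`, `cluster_label`).
#' @param k_hvg number of highly variable genes to keep; `Inf` keeps all.
#' @param gene_subset explicit gene ID set overriding HVG selection.
#' @param scale normalization scale factor.
#' @param denominator see [specificity_index()].
#' @return a [specificity_matrix()].
#' @export
compute_specificity <- function(m, ann, k_hvg = 3000L, gene_subset = NULL,
                                scale = 1e4,
                                denominator = c("all_cells", "within_cluster")) {
  norm <- normalize_counts(m, scale = scale)
  if (!is.null(gene_subset)) {
    keep <- intersect(rownames(norm), gene_subset)
    if (length(keep) < 1L) stop("gene_subset has no overlap with matrix")
    norm <- norm[keep, , drop = FALSE]
  } else if (is.finite(k_hvg) && k_hvg < nrow(norm)) {
    norm <- norm[select_hvgs(norm, k = k_hvg), , drop = FALSE]
    norm <- norm[order(rownames(norm)), , drop = FALSE]
  }
  cm <- cluster_means(norm, ann)
  specificity_index(cm$means, cm$cluster_sizes,
                    denominator = match.arg(denominator))
}
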