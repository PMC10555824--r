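#' Cross-species Pearson correlation of cell-type specificity profiles
#'
#' Correlates every species-1 cell type with every species-2 cell type over
#' the orthogroups shared by both specificity matrices (masked genes
#' excluded; optionally restricted to `gene_set`, e.g. a TF orthogroup
#' list).
#'
#' @param sp1,sp2 [specificity_matrix()] objects indexed by the same
#'   orthogroup IDs.
#' @param gene_set optional character vector restricting the orthogroups
#'   used.
#' @return types-1 x types-2 matrix of Pearson r; cell types whose profile
#'   has zero variance over the shared genes get `NA` entries (excluded from
#'   matching).
#' @export
correlate_celltypes <- function(sp1, sp2, gene_set = NULL) {
  stopifnot(inherits(sp1, "SpecificityMatrix"),
            inherits(sp2, "SpecificityMatrix"))
  shared <- intersect(rownames(sp1$values)[!sp1$masked],
                      rownames(sp2$values)[!sp2$masked])
  if (!is.null(gene_set)) shared <- intersect(shared, as.character(gene_set))
  if (length(shared) < 3L)
    stop("fewer than 3 shared genes between the two specificity matrices")
  suppressWarnings(stats::cor(sp1$values[shared, , drop = FALSE],
                              sp2$values[shared, , drop = FALSE]))
}

# argmax over a vector of correlations; exact ties broken by the
# lexicographically smallest name, flagged
best_hit <- function(r) {
  if (all(is.na(r))) return(NULL)
  m <- max(r, na.rm = TRUE)
  cand <- sort(names(r)[!is.na(r) & r == m])
  list(name = cand[1], r = m, tie = length(cand) > 1L)
}

#' Reciprocal-best-hit matching of cell types
#'
#' `(c1, c2)` is a matched pair iff `c2` maximizes row `c1` of the
#' correlation matrix and `c1` maximizes column `c2`. The output is a
#' partial matching: no cell type appears twice. Exact ties are broken by
#' lexicographic type label and flagged.
#'
#' @param corr correlation matrix from [correlate_celltypes()].
#' @return data frame with `type_s1`, `type_s2`, `r`, `tie`.
#' @export
reciprocal_best_hits <- function(corr) {
  rows <- lapply(seq_len(nrow(corr)), function(i) best_hit(corr[i, ]))
  cols <- lapply(seq_len(ncol(corr)), function(j) best_hit(corr[, j]))
  out <- list()
  for (i in seq_len(nrow(corr))) {
    bh <- rows[[i]]
    if (is.null(bh)) next
    j <- match(bh$name, colnames(corr))
    cb <- cols[[j]]
    if (!is.null(cb) && cb$name == rownames(corr)[i])
      out[[length(out) + 1L]] <- data.frame(
        type_s1 = rownames(corr)[i], type_s2 = bh$name, r = bh$r,
        tie = bh$tie || cb$tie, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(type_s1 = character(), type_s2 = character(),
                      r = numeric(), tie = logical()))
  do.call(rbind, out)
}

#' Full cross-species cell-type comparison
#'
#' Correlation matrix, reciprocal-best-hit pairs, and a joint dendrogram
#' over the union of both species' cell types (complete linkage at distance
#' `1 - r`) with multiscale bootstrap BP/AU support, resampling orthogroups.
#'
#' @param sp1,sp2 [specificity_matrix()] objects on shared orthogroup IDs.
#' @param gene_set optional orthogroup restriction (e.g. TF orthogroups).
#' @param gene_set_tag label recorded in the result.
#' @param species_names length-2 labels prefixed to the dendrogram leaves.
#' @param n_boot bootstrap replicates per scale; 0 skips the bootstrap.
#' @param scales multiscale resampling fractions.
#' @param seed RNG seed for the bootstrap.
#' @return a [homology_result()].
#' @export
compare_celltypes <- function(sp1, sp2, gene_set = NULL,
                              gene_set_tag = if (is.null(gene_set)) "all"
                                             else "restricted",
                              species_names = c("s1", "s2"),
                              n_boot = 1000L,
                              scales = seq(0.5, 1.4, by = 0.1),
                              seed = 1L) {
  corr <- correlate_celltypes(sp1, sp2, gene_set = gene_set)
  rbh <- reciprocal_best_hits(corr)

  shared <- intersect(rownames(sp1$values)[!sp1$masked],
                      rownames(sp2$values)[!sp2$masked])
  if (!is.null(gene_set)) shared <- intersect(shared, as.character(gene_set))
  joint <- cbind(sp1$values[shared, , drop = FALSE],
                 sp2$values[shared, , drop = FALSE])
  colnames(joint) <- c(paste(species_names[1], colnames(sp1$values), sep = "|"),
                       paste(species_names[2], colnames(sp2$values), sep = "|"))

  if (n_boot > 0L) {
    bs <- bootstrap_support(joint, n_boot = n_boot, scales = scales,
                            seed = seed)
    homology_result(corr, rbh, dendrogram = bs$dendrogram,
                    support = bs$support, n_boot = n_boot,
                    gene_set_tag = gene_set_tag)
  } else {
    homology_result(corr, rbh, dendrogram = build_dendrogram(joint),
                    support = NULL, n_boot = 0L, gene_set_tag = gene_set_tag)
  }
}

#' Write a HomologyResult to disk
#'
#' Emits the correlation matrix (TSV), the RBH pairs (TSV), the dendrogram
#' (Newick with BP/AU node labels when available) and a JSON summary.
#'
#' @param result a [homology_result()].
#' @param dir output directory.
#' @export
write_homology <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(type_s1 = rownames(result$corr), result$corr,
               check.names = FALSE),
    file.path(dir, "correlation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$rbh_pairs, file.path(dir, "rbh_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$dendrogram) && !is.null(result$support))
    write_newick(result$dendrogram, result$support,
                 file.path(dir, "dendrogram.nwk"))
  jsonlite::write_json(
    list(gene_set_tag = result$gene_set_tag, n_boot = result$n_boot,
         n_rbh_pairs = nrow(result$rbh_pairs),
         support = result$support),
    file.path(dir, "homology.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
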