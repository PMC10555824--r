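# Per-gene two-sided Wilcoxon rank-sum (Mann-Whitney) with normal
# approximation and tie correction, no continuity correction. `x` is a
# genes x cells matrix (dense or sparse), `in_group` a logical over cells.
wilcox_rows <- function(x, in_group) {
  x <- as.matrix(x)
  n <- ncol(x)
  n1 <- sum(in_group)
  n2 <- n - n1
  stats_one <- function(v) {
    r <- rank(v)
    ties <- rle(sort(v))$lengths
    c(sum(r[in_group]), sum(ties^3 - ties))
  }
  st <- t(apply(x, 1, stats_one))
  U <- st[, 1] - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - st[, 2] / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (U - n1 * n2 / 2) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, 2 * stats::pnorm(-abs(z)), 1)
  list(U = U, z = z, p = p)
}

#' One-vs-rest Wilcoxon marker detection for one cluster
#'
#' Tests every gene for differential expression between the cells of
#' `cluster` and all remaining cells, using a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction). Genes where neither
#' group reaches `min_pct` expressing cells are not tested and do not enter
#' the Bonferroni denominator (the `"all"` option divides by all genes
#' instead). The log fold change is computed on de-normalized expression
#' means, `logFC = log_base((mean(expm1(in)) + pseudocount) /
#' (mean(expm1(out)) + pseudocount))`.
#'
#' A gene passes when `logFC >= logfc_threshold`, the pre-filter holds, and
#' the Bonferroni-adjusted p-value is below `alpha`.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param ann annotation data frame (`cell_id`, `cluster_label`).
#' @param cluster the cluster label to test (needs >= 3 cells in the cluster
#'   and >= 3 outside it).
#' @param min_pct pre-filter: max of in/out expressing fractions must reach
#'   this (default 0.1).
#' @param logfc_threshold minimum log fold change (default 0.25).
#' @param alpha adjusted p-value cutoff (default 0.01).
#' @param pseudocount,base log fold change convention (defaults: natural log,
#'   pseudocount 1).
#' @param bonferroni `"tested"` (genes passing the pre-filter; default) or
#'   `"all"` genes as the correction denominator.
#' @return data frame with one row per tested gene: `gene`, `cluster`,
#'   `logfc`, `pct_in`, `pct_out`, `p_val`, `p_adj`, `pass`, sorted by
#'   p-value then decreasing logFC; `attr(, "n_tested")` and
#'   `attr(, "n_prefiltered")` record the pre-filter.
#' @export
rank_markers <- function(norm, ann, cluster, min_pct = 0.1,
                         logfc_threshold = 0.25, alpha = 0.01,
                         pseudocount = 1, base = exp(1),
                         bonferroni = c("tested", "all")) {
  bonferroni <- match.arg(bonferroni)
  lab <- ann$cluster_label[match(colnames(norm), ann$cell_id)]
  if (anyNA(lab)) stop("unlabelled cell(s) in matrix")
  if (!cluster %in% lab) stop("unknown cluster label: ", cluster)
  in_group <- lab == cluster
  if (sum(in_group) < 3L || sum(!in_group) < 3L)
    stop("cluster and its complement each need >= 3 cells")

  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  nz <- norm > 0
  pct_in <- Matrix::rowSums(nz[, in_group, drop = FALSE]) / n1
  pct_out <- Matrix::rowSums(nz[, !in_group, drop = FALSE]) / n2
  tested <- pmax(pct_in, pct_out) >= min_pct
  n_tested <- sum(tested)
  if (n_tested == 0L) {
    out <- data.frame(gene = character(), cluster = character(),
                      logfc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_val = numeric(),
                      p_adj = numeric(), pass = logical())
    attr(out, "n_tested") <- 0L
    attr(out, "n_prefiltered") <- nrow(norm)
    return(out)
  }

  sub <- norm[tested, , drop = FALSE]
  expr <- sub
  expr@x <- expm1(expr@x)
  mean_in <- Matrix::rowSums(expr[, in_group, drop = FALSE]) / n1
  mean_out <- Matrix::rowSums(expr[, !in_group, drop = FALSE]) / n2
  logfc <- (log(mean_in + pseudocount) - log(mean_out + pseudocount)) /
    log(base)

  w <- wilcox_rows(sub, in_group)
  denom <- if (bonferroni == "tested") n_tested else nrow(norm)
  p_adj <- pmin(1, w$p * denom)

  out <- data.frame(gene = rownames(sub), cluster = cluster,
                    logfc = logfc, pct_in = pct_in[tested],
                    pct_out = pct_out[tested], p_val = w$p, p_adj = p_adj,
                    pass = logfc >= logfc_threshold & p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_val, -out$logfc), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  attr(out, "n_prefiltered") <- nrow(norm) - n_tested
  out
}

#' Marker detection for every cluster
#'
#' Runs [rank_markers()] one-vs-rest for each cluster label present.
#'
#' @inheritParams rank_markers
#' @param ... passed to [rank_markers()].
#' @return a single data frame of all clusters' tested genes.
#' @export
find_all_markers <- function(norm, ann, ...) {
  lab <- ann$cluster_label[match(colnames(norm), ann$cell_id)]
  clusters <- sort(unique(lab))
  res <- lapply(clusters, function(cl) rank_markers(norm, ann, cl, ...))
  do.call(rbind, res)
}
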