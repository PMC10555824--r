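# Multiscale-bootstrap AU fit for one node: weighted least squares of
# z_r = qnorm(1 - BP(r)) on (sqrt(r), 1/sqrt(r)) over scales with
# 0 < BP < 1, binomial weights; AU = 1 - pnorm(v - c).
au_fit <- function(bp, scales, n_boot) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 2L) {
    if (all(bp >= 1)) return(list(au = 100, flag = "clamped"))
    if (all(bp <= 0)) return(list(au = 0, flag = "clamped"))
    return(list(au = NA_real_, flag = "unavailable"))
  }
  r <- scales[use]
  z <- stats::qnorm(1 - bp[use])
  X <- cbind(v = sqrt(r), c = 1 / sqrt(r))
  w <- n_boot * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  XtW <- t(X * w)
  coef <- solve(XtW %*% X, XtW %*% z)
  list(au = unname((1 - stats::pnorm(coef["v", 1] - coef["c", 1])) * 100),
       flag = "fitted")
}

#' Multiscale bootstrap support (BP and AU) for a profile dendrogram
#'
#' Builds the complete-linkage dendrogram on the full gene set, then, for
#' each scale `r`, draws `n_boot` resamples of `ceiling(r * G)` genes with
#' replacement, reclusters, and records for every internal node the fraction
#' of replicates whose dendrogram contains the node's exact leaf set (the
#' bootstrap proportion, BP). The reported BP is the proportion at `r = 1`.
#' The approximately unbiased (AU) support comes from a weighted
#' least-squares fit of `qnorm(1 - BP(r))` against `v*sqrt(r) + c/sqrt(r)`
#' over scales with interior BP; `AU = (1 - pnorm(v - c)) * 100`. Nodes with
#' BP 0 or 1 at every scale are clamped to 0 or 100 and flagged; nodes with
#' fewer than two usable scales keep their BP but get `AU = NA`, flagged
#' `"unavailable"`.
#'
#' Replicate RNG streams are derived as `seed + (scale index - 1) * n_boot +
#' replicate`, so each replicate is reproducible in isolation.
#'
#' @param profiles genes x leaves matrix of (specificity) profiles.
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param scales resampling fractions (default 0.5 to 1.4 by 0.1).
#' @param seed integer RNG seed.
#' @return list with `dendrogram` (`hclust`), `support` (data frame: node,
#'   clade, `bp`, `au`, `flag`; percentages), `bp_by_scale` (nodes x scales),
#'   `scales`, `n_boot`, `n_failed` (replicates per scale with undefined
#'   correlations, excluded from the denominator).
#' @export
bootstrap_support <- function(profiles, n_boot = 1000L,
                              scales = seq(0.5, 1.4, by = 0.1),
                              seed = 1L) {
  if (ncol(profiles) < 2L) stop("need at least 2 leaves")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  G <- nrow(profiles)
  hc <- build_dendrogram(profiles)
  keys <- clade_keys(hc)
  n_nodes <- length(keys)

  counts <- matrix(0L, n_nodes, length(scales))
  n_failed <- integer(length(scales))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * G)
    for (b in seq_len(n_boot)) {
      set.seed((seed + (si - 1L) * n_boot + b) %% .Machine$integer.max)
      idx <- sample.int(G, m, replace = TRUE)
      cc <- suppressWarnings(stats::cor(profiles[idx, , drop = FALSE]))
      if (any(!is.finite(cc))) {
        n_failed[si] <- n_failed[si] + 1L
        next
      }
      rep_keys <- clade_keys(complete_linkage(1 - cc))
      hit <- match(rep_keys, keys)
      hit <- hit[!is.na(hit)]
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  denom <- pmax(n_boot - n_failed, 1L)
  bp <- sweep(counts, 2, denom, `/`)

  i1 <- which.min(abs(scales - 1))
  fits <- apply(bp, 1, au_fit, scales = scales, n_boot = n_boot)
  support <- data.frame(
    node = seq_len(n_nodes),
    clade = vapply(clade_leaf_sets(hc), paste, "", collapse = ","),
    bp = bp[, i1] * 100,
    au = vapply(fits, function(f) f$au, 0),
    flag = vapply(fits, function(f) f$flag, ""),
    stringsAsFactors = FALSE)
  colnames(bp) <- sprintf("r%.1f", scales)
  list(dendrogram = hc, support = support, bp_by_scale = bp,
       scales = scales, n_boot = n_boot, n_failed = n_failed)
}

#' Write a support-annotated dendrogram as Newick
#'
#' Internal node labels carry `BP/AU` (rounded percent).
#'
#' @param hc the `hclust` tree.
#' @param support the `support` data frame from [bootstrap_support()].
#' @param path output file.
#' @export
write_newick <- function(hc, support, path) {
  phy <- ape::as.phylo(hc)
  pp <- ape::prop.part(phy)
  tips <- attr(pp, "labels")
  keys <- vapply(clade_leaf_sets(hc), paste, "", collapse = "\t")
  node_lab <- character(length(pp))
  for (k in seq_along(pp)) {
    key <- paste(sort(tips[pp[[k]]]), collapse = "\t")
    hit <- match(key, keys)
    node_lab[k] <- if (!is.na(hit))
      sprintf("%.0f/%.0f", support$bp[hit], support$au[hit]) else ""
  }
  phy$node.label <- node_lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
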