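#' Pearson correlation distance between profile columns
#'
#' `d = 1 - r`, bounded in `[0, 2]`.
#'
#' @param profiles numeric matrix, genes x leaves (leaves in columns, named).
#' @return symmetric distance matrix.
#' @export
cor_distance <- function(profiles) {
  d <- 1 - suppressWarnings(stats::cor(profiles))
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("undefined distance between '%s' and '%s'",
                 rownames(d)[bad[1, 1]], colnames(d)[bad[1, 2]]))
  d
}

#' Complete-linkage hierarchical clustering with a deterministic tie-break
#'
#' Agglomerates leaves under complete linkage (cluster distance = maximum
#' pairwise leaf distance). When several pairs are exactly tied at the
#' minimal distance, the pair whose representative leaf labels (the
#' lexicographically smallest label in each cluster) sort first is merged,
#' so the result is independent of input order.
#'
#' @param d symmetric distance matrix with leaf labels as dimnames.
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) stop("need at least 2 leaves")
  if (any(!is.finite(d))) stop("non-finite distances")

  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  id <- -seq_len(n)            # hclust codes: negative leaf, positive merge
  rep_lab <- labels            # smallest leaf label per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    Dv <- D
    Dv[!active, ] <- Inf
    Dv[, !active] <- Inf
    mval <- min(Dv)
    cand <- which(Dv == mval & upper.tri(Dv), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      a <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      b <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      cand <- cand[order(a, b), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]

    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- mval

    new_d <- pmax(D[i, ], D[j, ])
    D[i, ] <- new_d
    D[, i] <- new_d
    D[i, i] <- Inf
    active[j] <- FALSE
    id[i] <- step
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
  }

  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = labels,
                 method = "complete", dist.method = "1 - Pearson r",
                 call = match.call()),
            class = "hclust")
}

#' Leaf sets of every internal node
#'
#' @param hc an `hclust` object.
#' @return list (one element per merge) of sorted leaf-label vectors.
#' @export
clade_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  get <- function(code) {
    if (code < 0L) hc$labels[-code] else sets[[code]]
  }
  for (k in seq_len(nrow(hc$merge)))
    sets[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
  sets
}

clade_keys <- function(hc) {
  vapply(clade_leaf_sets(hc), paste, "", collapse = "\t")
}

#' Cell-type dendrogram from specificity profiles
#'
#' Complete-linkage tree over profile columns at distance `1 - Pearson r`.
#'
#' @param profiles genes x leaves matrix (e.g. joint cross-species
#'   specificity profiles over shared orthogroups).
#' @return an `hclust` object.
#' @export
build_dendrogram <- function(profiles) {
  complete_linkage(cor_distance(profiles))
}
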