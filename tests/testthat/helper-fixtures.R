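# Small simulated atlas used across tests. base_mean is raised relative to
# the full-scale defaults so that cells clear the 200-UMI QC cut at the
# reduced orthogroup count.
small_sim_config <- function(...) {
  args <- list(n_orthogroups = 120L, n_shared_families = 4L,
               n_private_s1 = 1L, n_private_s2 = 1L, cells_per_type = 40L,
               frac_marker_genes = 0.05, fold_up = 8, divergence = 0.2,
               nb_dispersion = 0.5, libsize_sigma = 0.2, base_mean = 3,
               seed = 42L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# dense matrix -> CountMatrix with auto gene/cell names
toy_counts <- function(m, species = "s1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  count_matrix(m, species = species)
}

# 12-cell QC toy: cell "low" has 150 total UMIs, cell "mito" has a 12%
# mitochondrial fraction, gene "g_rare" is expressed in only 4 cells, and
# gene "g_five" in exactly 5.
qc_toy_matrix <- function() {
  cells <- sprintf("c%02d", 1:12)
  genes <- c(sprintf("g%d", 1:7), "g_rare", "g_five", "MT-1")
  m <- matrix(0, length(genes), 12, dimnames = list(genes, cells))
  m[sprintf("g%d", 1:7), ] <- 50
  m["MT-1", ] <- 10
  m["g_rare", 1:4] <- 1
  m["g_five", 1:5] <- 1
  # c05: low UMI (7*20 + 10 = 150)
  m[sprintf("g%d", 1:7), 5] <- 20
  m["MT-1", 5] <- 10
  # c06: high mito (48 / (350 + 48) = 0.1206)
  m["MT-1", 6] <- 48
  count_matrix(m, species = "toy")
}

# independent brute-force complete linkage: recompute every cluster distance
# from scratch as the max over leaf pairs (O(n^3) per instance)
brute_complete_linkage <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dist_ij <- max(d[clusters[[i]], clusters[[j]]])
      if (dist_ij < best) { best <- dist_ij; bi <- i; bj <- j }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    heights <- c(heights, best)
    clades <- c(clades, list(sort(labels[merged])))
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  list(heights = heights, clades = clades)
}
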