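test_that("normalization follows the closed form and its invariances", {
  m <- toy_counts(matrix(c(1, 0, 3), 3, 1))
  norm <- normalize_counts(m, scale = 1e4)
  expect_equal(as.vector(norm), c(log1p(2500), 0, log1p(7500)))

  # doubling all counts of a cell changes nothing
  m2 <- toy_counts(matrix(c(2, 0, 6), 3, 1))
  expect_equal(as.vector(normalize_counts(m2)), as.vector(norm))

  # sparsity pattern preserved
  cfg <- small_sim_config(cells_per_type = 10L)
  atlas <- simulate_atlas(cfg)
  n <- normalize_counts(atlas$s1)
  expect_identical(n@i, atlas$s1$counts@i)
  expect_identical(n@p, atlas$s1$counts@p)
})

test_that("HVG selection clamps, is deterministic, and shuns constants", {
  m <- toy_counts(matrix(rpois(10 * 30, 5) + 1, 10, 30))
  norm <- normalize_counts(m)
  expect_warning(hv <- select_hvgs(norm, k = 3000), "only 10 genes")
  expect_length(hv, 10)

  # a constant gene is never ranked above any positive-variance gene
  d <- withr::with_seed(3, matrix(runif(40 * 60), 40, 60,
                                  dimnames = list(sprintf("g%02d", 1:40),
                                                  NULL)))
  d[1, ] <- 0.5                     # constant normalized values
  ranked <- select_hvgs(d, k = 40, n_bins = 5)
  expect_equal(ranked[40], "g01")
})

test_that("simulated program genes are strongly enriched among top HVGs", {
  cfg <- sim_config(n_orthogroups = 1000L, n_shared_families = 4L,
                    n_private_s1 = 0L, n_private_s2 = 0L,
                    cells_per_type = 60L, frac_marker_genes = 0.01,
                    fold_up = 8, divergence = 0, base_mean = 1, seed = 21L)
  atlas <- simulate_atlas(cfg)
  meta <- collapse_to_metagenes(atlas$s1, atlas$ortho, "s1")
  markers <- as.character(sort(unique(unlist(atlas$truth$marker_sets$s1))))
  k <- length(markers)
  top <- select_hvgs(normalize_counts(meta), k = k)
  enrichment <- (mean(top %in% markers)) / (k / cfg$n_orthogroups)
  expect_gte(enrichment, 5)
})

test_that("cluster means match a brute-force group-by", {
  x <- withr::with_seed(8, matrix(rpois(12 * 20, 4), 12, 20))
  m <- toy_counts(x)
  norm <- normalize_counts(m)
  ann <- data.frame(cell_id = cell_ids(m),
                    cluster_label = rep(c("a", "b", "c"),
                                        times = c(1, 9, 10)))
  cm <- cluster_means(norm, ann)
  dense <- as.matrix(norm)
  for (t in c("a", "b", "c")) {
    cells <- ann$cell_id[ann$cluster_label == t]
    expect_equal(cm$means[, t], rowMeans(dense[, cells, drop = FALSE]))
  }
  # single-cell cluster mean equals that cell's values
  expect_equal(cm$means[, "a"], dense[, ann$cell_id[ann$cluster_label == "a"]])
  expect_equal(cm$cluster_sizes, c(a = 1L, b = 9L, c = 10L))
})

test_that("specificity index matches its defining identities", {
  # equal mean in every cluster (equal sizes) -> s = 1 everywhere
  means <- matrix(3, 2, 4, dimnames = list(c("g1", "g2"), paste0("t", 1:4)))
  sizes <- stats::setNames(rep(10L, 4), paste0("t", 1:4))
  sp <- specificity_index(means, sizes)
  expect_true(all(sp$values == 1))

  # weighted denominator: sizes 10 and 30, means 4 and 0 -> gbar = 1
  means2 <- matrix(c(4, 0), 1, 2, dimnames = list("g", c("t1", "t2")))
  sizes2 <- c(t1 = 10L, t2 = 30L)
  sp2 <- specificity_index(means2, sizes2)
  expect_equal(as.vector(sp2$values), c(4, 0))

  # algebraic identity for every unmasked gene
  m3 <- withr::with_seed(2, matrix(rpois(30 * 8, 2), 30, 8,
                                   dimnames = list(paste0("g", 1:30),
                                                   paste0("t", 1:8))))
  sizes3 <- stats::setNames(sample(5:40, 8), paste0("t", 1:8))
  sp3 <- specificity_index(m3, sizes3)
  ok <- !sp3$masked
  resid <- abs(sp3$values[ok, ] %*% (sizes3 / sum(sizes3)) - 1)
  expect_lt(max(resid), 1e-9)

  # zero-overall-mean genes are masked, not divided
  m4 <- rbind(m3, gz = 0)
  sp4 <- specificity_index(m4, sizes3)
  expect_true(sp4$masked["gz"])
  expect_true(all(is.na(sp4$values["gz", ])))

  # invariance to global rescaling of the normalized matrix
  sp5 <- specificity_index(m3 * 7.3, sizes3)
  expect_equal(sp5$values, sp3$values)
})

test_that("the literal within-cluster denominator reads N / n_c", {
  means <- matrix(c(4, 2, 3, 5), 2, 2,
                  dimnames = list(c("g1", "g2"), c("t1", "t2")))
  sizes <- c(t1 = 10L, t2 = 30L)
  sp <- specificity_index(means, sizes, denominator = "within_cluster")
  expect_equal(unname(sp$values[1, ]), c(40 / 10, 40 / 30))
  expect_equal(unname(sp$values[2, ]), c(40 / 10, 40 / 30))
})

test_that("the staged pipeline equals a one-pass brute-force computation", {
  set.seed(13)
  n_genes <- 24; n_cells <- 50
  genes <- sprintf("gene%02d", seq_len(n_genes))
  x <- matrix(rpois(n_genes * n_cells, 3) + 1, n_genes, n_cells,
              dimnames = list(genes, sprintf("cell%02d", seq_len(n_cells))))
  og <- split(genes, rep(1:12, each = 2))  # 12 orthogroups of 2 paralogues
  om <- ortho_map(og, as.list(sprintf("x%02d", 1:12)))
  lab <- rep(c("t1", "t2", "t3"), times = c(10, 15, 25))
  ann <- data.frame(cell_id = colnames(x), cluster_label = lab)

  staged <- compute_specificity(
    collapse_to_metagenes(count_matrix(x), om, "s1"), ann, k_hvg = Inf)

  # brute force, cell by cell, in plain loops
  collapsed <- matrix(0, 12, n_cells)
  for (o in 1:12) for (cell in 1:n_cells)
    collapsed[o, cell] <- sum(x[og[[o]], cell])
  norm <- matrix(0, 12, n_cells)
  for (cell in 1:n_cells)
    norm[, cell] <- log1p(collapsed[, cell] * 1e4 / sum(collapsed[, cell]))
  types <- sort(unique(lab))
  s <- matrix(0, 12, length(types))
  for (o in 1:12) {
    gbar <- mean(norm[o, ])
    for (ti in seq_along(types))
      s[o, ti] <- mean(norm[o, lab == types[ti]]) / gbar
  }
  expect_equal(unname(staged$values), s)
})
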