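spec_fixture <- function(values, sizes = NULL) {
  if (is.null(sizes))
    sizes <- stats::setNames(rep(10L, ncol(values)), colnames(values))
  specificity_matrix(values, sizes)
}

test_that("correlation reaches the exact endpoints", {
  v <- matrix(c(0, 1, 2, 3, 4,
                0, 1, 2, 3, 4), 5, 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  sp1 <- spec_fixture(v[, "a", drop = FALSE])
  sp2 <- spec_fixture(v[, "b", drop = FALSE])
  expect_equal(unname(correlate_celltypes(sp1, sp2)[1, 1]), 1)

  neg <- matrix(4 - v[, 1], 5, 1, dimnames = list(paste0("g", 1:5), "c"))
  expect_equal(unname(correlate_celltypes(sp1, spec_fixture(neg))[1, 1]), -1)

  expect_error(correlate_celltypes(
    spec_fixture(v[1:2, "a", drop = FALSE]),
    spec_fixture(v[1:2, "b", drop = FALSE])), "fewer than 3 shared genes")
})

test_that("reciprocal best hits follow the argmax logic", {
  corr <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
                 dimnames = list(c("a1", "a2"), c("b1", "b2")))
  rbh <- reciprocal_best_hits(corr)
  expect_equal(rbh$type_s1, c("a1", "a2"))
  expect_equal(rbh$type_s2, c("b1", "b2"))

  corr2 <- matrix(c(0.9, 0.2, 0.95, 0.1), 2, 2,
                  dimnames = list(c("a1", "a2"), c("b1", "b2")))
  rbh2 <- reciprocal_best_hits(corr2)
  expect_equal(nrow(rbh2), 1L)
  expect_equal(rbh2$type_s1, "a1")
  expect_equal(rbh2$type_s2, "b2")

  # exact ties break lexicographically and are flagged
  corr3 <- matrix(c(0.9, 0.1, 0.9, 0.1), 2, 2,
                  dimnames = list(c("a1", "a2"), c("b2", "b1")))
  rbh3 <- reciprocal_best_hits(corr3)
  expect_equal(rbh3$type_s2, "b1")
  expect_true(rbh3$tie)
})

test_that("RBH output is always a partial matching", {
  for (i in 1:50) {
    corr <- withr::with_seed(i, matrix(runif(30, -1, 1), 5, 6,
                                       dimnames = list(paste0("a", 1:5),
                                                       paste0("b", 1:6))))
    rbh <- reciprocal_best_hits(corr)
    expect_false(anyDuplicated(rbh$type_s1) > 0)
    expect_false(anyDuplicated(rbh$type_s2) > 0)
  }
})

test_that("correlation is symmetric under species swap", {
  set.seed(31)
  v1 <- matrix(runif(60), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("a", 1:6)))
  v2 <- matrix(runif(40), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("b", 1:4)))
  sp1 <- spec_fixture(v1); sp2 <- spec_fixture(v2)
  expect_equal(correlate_celltypes(sp1, sp2),
               t(correlate_celltypes(sp2, sp1)))
})

test_that("true pairs correlate more strongly than non-pairs", {
  atlas <- simulate_atlas(small_sim_config())
  meta1 <- collapse_to_metagenes(atlas$s1, atlas$ortho, "s1")
  meta2 <- collapse_to_metagenes(atlas$s2, atlas$ortho, "s2")
  sp1 <- compute_specificity(meta1, atlas$ann_s1, k_hvg = Inf)
  sp2 <- compute_specificity(meta2, atlas$ann_s2, k_hvg = Inf)
  corr <- correlate_celltypes(sp1, sp2)
  tp <- atlas$truth$true_pairs
  r_true <- corr[cbind(tp$type_s1, tp$type_s2)]
  non <- corr; non[cbind(tp$type_s1, tp$type_s2)] <- NA
  expect_gt(mean(r_true), mean(non, na.rm = TRUE))
})

test_that("forced topologies come out of complete linkage", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(clade_leaf_sets(hc)[[1]], c("A", "B"))

  # duplicated leaf merges first at height 0
  v <- matrix(c(1, 2, 3, 1, 2, 3, 3, 1, 0), 3, 3,
              dimnames = list(paste0("g", 1:3), c("L1", "L2", "L3")))
  hc2 <- build_dendrogram(v)
  expect_equal(hc2$height[1], 0)
  expect_equal(clade_leaf_sets(hc2)[[1]], c("L1", "L2"))
})

test_that("complete linkage matches brute-force and hclust oracles", {
  for (i in 1:100) {
    d <- withr::with_seed(1000 + i, {
      x <- matrix(runif(64), 8, 8)
      d <- (x + t(x)) / 2
      diag(d) <- 0
      dimnames(d) <- list(letters[1:8], letters[1:8])
      d
    })
    mine <- complete_linkage(d)
    brute <- brute_complete_linkage(d)
    expect_equal(mine$height, brute$heights)
    expect_identical(clade_leaf_sets(mine), brute$clades)
    ref <- stats::hclust(stats::as.dist(d), method = "complete")
    expect_equal(mine$height, ref$height)
  }
})

test_that("undefined distances raise an error naming the pair", {
  v <- matrix(c(1, 1, 1, 0, 1, 2), 3, 2,
              dimnames = list(paste0("g", 1:3), c("flat", "ok")))
  expect_error(cor_distance(v), "flat")
})

test_that("an exactly duplicated profile keeps BP = 100 at every scale", {
  set.seed(41)
  prof <- matrix(runif(150 * 6), 150, 6,
                 dimnames = list(NULL, c("dupA", "dupB", paste0("t", 1:4))))
  prof[, "dupB"] <- prof[, "dupA"]
  bs <- bootstrap_support(prof, n_boot = 100, seed = 3)
  node <- match("dupA\tdupB", orthocell:::clade_keys(bs$dendrogram))
  expect_false(is.na(node))
  expect_true(all(bs$bp_by_scale[node, ] == 1))
  expect_equal(bs$support$bp[node], 100)
  expect_equal(bs$support$au[node], 100)
  expect_equal(bs$support$flag[node], "clamped")
})

test_that("the multiscale AU fit honours its fixed points", {
  # BP = 0.5 at every scale forces v = c = 0, hence AU = 50
  fit <- orthocell:::au_fit(rep(0.5, 10), seq(0.5, 1.4, by = 0.1),
                            n_boot = 1000)
  expect_equal(fit$au, 50)
  expect_equal(fit$flag, "fitted")

  # curvature-free nodes (BP(r) = 1 - pnorm(v * sqrt(r))) have AU = BP(1)
  scales <- seq(0.5, 1.4, by = 0.1)
  for (v in c(-0.8, 0.3, 1.5)) {
    bp <- 1 - stats::pnorm(v * sqrt(scales))
    fit <- orthocell:::au_fit(bp, scales, 1000)
    expect_equal(fit$au, (1 - stats::pnorm(v)) * 100, tolerance = 1e-6)
  }

  # degenerate rows
  expect_equal(orthocell:::au_fit(rep(1, 10), seq(0.5, 1.4, 0.1), 1000)$au, 100)
  expect_equal(orthocell:::au_fit(rep(0, 10), seq(0.5, 1.4, 0.1), 1000)$au, 0)
  expect_equal(orthocell:::au_fit(c(0, 1, rep(0, 8)), seq(0.5, 1.4, 0.1),
                                  1000)$flag, "unavailable")
})

test_that("BP is invariant to leaf-label permutation of the profiles", {
  set.seed(17)
  prof <- matrix(runif(80 * 5), 80, 5,
                 dimnames = list(NULL, paste0("t", 1:5)))
  a <- bootstrap_support(prof, n_boot = 60, seed = 9)
  b <- bootstrap_support(prof[, c(3, 1, 5, 2, 4)], n_boot = 60, seed = 9)
  key <- function(bs) {
    k <- orthocell:::clade_keys(bs$dendrogram)
    stats::setNames(bs$support$bp, k)[order(k)]
  }
  expect_equal(key(a), key(b))
})

test_that("raising simulator divergence never strengthens true-pair correlation", {
  mean_true_r <- vapply(c(0, 0.5, 1), function(dv) {
    atlas <- simulate_atlas(small_sim_config(divergence = dv,
                                             cells_per_type = 25L))
    sp1 <- compute_specificity(
      collapse_to_metagenes(atlas$s1, atlas$ortho, "s1"),
      atlas$ann_s1, k_hvg = Inf)
    sp2 <- compute_specificity(
      collapse_to_metagenes(atlas$s2, atlas$ortho, "s2"),
      atlas$ann_s2, k_hvg = Inf)
    corr <- correlate_celltypes(sp1, sp2)
    tp <- atlas$truth$true_pairs
    mean(corr[cbind(tp$type_s1, tp$type_s2)])
  }, 0)
  expect_true(all(diff(mean_true_r) <= 0))
})

test_that("a homology result round-trips to disk including Newick support", {
  atlas <- simulate_atlas(small_sim_config(cells_per_type = 20L))
  sp1 <- compute_specificity(
    collapse_to_metagenes(atlas$s1, atlas$ortho, "s1"), atlas$ann_s1,
    k_hvg = Inf)
  sp2 <- compute_specificity(
    collapse_to_metagenes(atlas$s2, atlas$ortho, "s2"), atlas$ann_s2,
    k_hvg = Inf)
  res <- compare_celltypes(sp1, sp2, n_boot = 30, seed = 2)
  d <- withr::local_tempdir()
  write_homology(res, d)
  expect_true(all(file.exists(file.path(
    d, c("correlation.tsv", "rbh_pairs.tsv", "dendrogram.nwk",
         "homology.json")))))
  phy <- ape::read.tree(file.path(d, "dendrogram.nwk"))
  expect_setequal(phy$tip.label,
                  c(paste0("s1|", colnames(sp1$values)),
                    paste0("s2|", colnames(sp2$values))))
  expect_true(any(grepl("^\\d+/\\d+$", phy$node.label)))
})
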