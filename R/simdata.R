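#' Configuration for the paired-species atlas simulator
#'
#' Defines the study conditions for a synthetic two-species single-cell
#' atlas with known orthology and known cell-type homology: a forest of
#' orthogroups with optional lineage-specific duplications, cell-type
#' expression programs shared between homologous type "families", and
#' negative-binomial UMI counts with log-normal library-size variation.
#'
#' @param n_orthogroups number of orthogroups (shared meta-gene indices).
#' @param p_dup_s1,p_dup_s2 probability that an orthogroup underwent one
#'   duplication in the respective species (orthogroup sizes stay in 1..2).
#' @param n_shared_families number of homologous cell-type families; each
#'   contributes exactly one cell type per species.
#' @param n_private_s1,n_private_s2 species-specific cell types without a
#'   homologue in the other species.
#' @param cells_per_type cells simulated per cell type.
#' @param frac_marker_genes fraction of orthogroups assigned as a type's
#'   expression-program (marker) genes.
#' @param fold_up multiplicative elevation of a program gene's mean in its
#'   own type, relative to `base_mean`.
#' @param divergence in `[0,1]`: fraction of each shared family's program
#'   orthogroups re-drawn independently per species (0 = identical programs,
#'   1 = independent programs).
#' @param nb_dispersion negative-binomial dispersion `alpha` with
#'   `variance = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param libsize_sigma log-normal sigma of the per-cell library-size factor.
#' @param mito_frac_mean mean fraction of a cell's UMIs coming from the
#'   dedicated mitochondrial genes.
#' @param base_mean median baseline expected UMI count per orthogroup per
#'   cell (at library factor 1).
#' @param base_mean_sigma log-normal sigma of per-orthogroup baseline means
#'   around `base_mean`, emulating the wide abundance spectrum of real
#'   transcriptomes; 0 gives every orthogroup the same baseline.
#' @param n_mito_genes number of dedicated `MT-` prefixed genes per species.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   atlases.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_orthogroups = 1500L,
                       p_dup_s1 = 0.15, p_dup_s2 = 0.15,
                       n_shared_families = 14L,
                       n_private_s1 = 2L, n_private_s2 = 2L,
                       cells_per_type = 200L,
                       frac_marker_genes = 0.02,
                       fold_up = 8,
                       divergence = 0.2,
                       nb_dispersion = 0.5,
                       libsize_sigma = 0.35,
                       mito_frac_mean = 0.05,
                       base_mean = 0.5,
                       base_mean_sigma = 0.5,
                       n_mito_genes = 10L,
                       seed = 1L) {
  cfg <- list(n_orthogroups = as.integer(n_orthogroups),
              p_dup_s1 = p_dup_s1, p_dup_s2 = p_dup_s2,
              n_shared_families = as.integer(n_shared_families),
              n_private_s1 = as.integer(n_private_s1),
              n_private_s2 = as.integer(n_private_s2),
              cells_per_type = as.integer(cells_per_type),
              frac_marker_genes = frac_marker_genes,
              fold_up = fold_up, divergence = divergence,
              nb_dispersion = nb_dispersion,
              libsize_sigma = libsize_sigma,
              mito_frac_mean = mito_frac_mean,
              base_mean = base_mean,
              base_mean_sigma = base_mean_sigma,
              n_mito_genes = as.integer(n_mito_genes),
              seed = as.integer(seed))
  for (p in c("p_dup_s1", "p_dup_s2", "divergence", "mito_frac_mean"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$frac_marker_genes < 0 || cfg$frac_marker_genes > 1)
    stop("frac_marker_genes must be in [0, 1]")
  for (p in c("n_orthogroups", "n_shared_families", "cells_per_type"))
    if (cfg[[p]] < 1L) stop(p, " must be >= 1")
  if (cfg$n_private_s1 < 0L || cfg$n_private_s2 < 0L)
    stop("private type counts must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$libsize_sigma < 0) stop("libsize_sigma must be >= 0")
  if (cfg$base_mean <= 0) stop("base_mean must be > 0")
  if (cfg$base_mean_sigma < 0) stop("base_mean_sigma must be >= 0")
  if (cfg$seed < 0L || cfg$seed > .Machine$integer.max - 10L)
    stop("seed out of range")
  structure(cfg, class = "SimConfig")
}

sim_type_labels <- function(config) {
  fam <- sprintf("F%02d", seq_len(config$n_shared_families))
  list(s1 = c(fam, if (config$n_private_s1 > 0)
                sprintf("S1P%d", seq_len(config$n_private_s1))),
       s2 = c(fam, if (config$n_private_s2 > 0)
                sprintf("S2P%d", seq_len(config$n_private_s2))))
}

#' Simulate the two-species gene forest
#'
#' Draws, per orthogroup and species, a single possible duplication round
#' (Bernoulli `p_dup`), so orthogroup sizes are 1 or 2 per side and the map
#' exercises 1:1, 1:2, 2:1 and 2:2 orthologies.
#'
#' @param config a [sim_config()].
#' @return an [ortho_map()] with deterministic, unique gene IDs.
#' @export
simulate_gene_forest <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_orthogroups
  withr::with_seed(config$seed, {
    dup1 <- stats::rbinom(n, 1L, config$p_dup_s1)
    dup2 <- stats::rbinom(n, 1L, config$p_dup_s2)
  })
  mk <- function(prefix, dup) {
    lapply(seq_len(n), function(i)
      sprintf("%sg%04d%s", prefix, i, if (dup[i]) c("a", "b") else "a"))
  }
  ortho_map(mk("s1", dup1), mk("s2", dup2),
            species = c("s1", "s2"), provenance = "simulated")
}

#' Simulate cell-type expression programs
#'
#' Every orthogroup gets a baseline expected expression drawn once from
#' `LogNormal(log(base_mean), base_mean_sigma)`, emulating the broad
#' abundance spectrum of real transcriptomes. Each cell type is then
#' assigned a set of marker orthogroups whose expected expression is
#' elevated `fold_up`-fold over that baseline in the type itself. Types
#' belonging to the same shared family keep a
#' `(1 - divergence)` fraction of their marker orthogroups in common between
#' the species; the rest are re-drawn independently. Within an orthogroup
#' the expected expression is split across paralogues by Dirichlet(1,...,1)
#' weights drawn once.
#'
#' @param config a [sim_config()].
#' @param ortho the [simulate_gene_forest()] output.
#' @return a `SimTruth` list: per-species program tables (orthogroups x
#'   types), paralogue split weights, marker sets, true homologous pairs.
#' @export
simulate_programs <- function(config, ortho) {
  stopifnot(inherits(config, "SimConfig"), inherits(ortho, "OrthoMap"))
  n <- config$n_orthogroups
  m <- round(config$frac_marker_genes * n)
  if (m < 1) stop("no program genes: frac_marker_genes * n_orthogroups < 1")
  labels <- sim_type_labels(config)

  withr::with_seed(config$seed + 1L, {
    og_base <- stats::rlnorm(n, log(config$base_mean),
                             config$base_mean_sigma)
    draw_family <- function() {
      base <- sample.int(n, m)
      keep <- round((1 - config$divergence) * m)
      shared <- base[seq_len(keep)]
      redraw <- function() {
        if (m == keep) return(shared)
        sort(c(shared, sample(setdiff(seq_len(n), shared), m - keep)))
      }
      list(s1 = redraw(), s2 = redraw())
    }
    fam_sets <- replicate(config$n_shared_families, draw_family(),
                          simplify = FALSE)
    priv1 <- replicate(config$n_private_s1, sort(sample.int(n, m)),
                       simplify = FALSE)
    priv2 <- replicate(config$n_private_s2, sort(sample.int(n, m)),
                       simplify = FALSE)
    split_w <- function(genes) {
      w <- lapply(lengths(genes), function(k) {
        g <- stats::rgamma(k, shape = 1)
        g / sum(g)
      })
      stats::setNames(unlist(w, use.names = FALSE),
                      unlist(genes, use.names = FALSE))
    }
    w1 <- split_w(ortho$genes_s1)
    w2 <- split_w(ortho$genes_s2)
  })

  marker_sets <- list(
    s1 = stats::setNames(c(lapply(fam_sets, `[[`, "s1"), priv1), labels$s1),
    s2 = stats::setNames(c(lapply(fam_sets, `[[`, "s2"), priv2), labels$s2))
  program <- function(sets) {
    p <- matrix(og_base, nrow = n, ncol = length(sets),
                dimnames = list(as.character(seq_len(n)), names(sets)))
    for (t in names(sets)) p[sets[[t]], t] <- og_base[sets[[t]]] * config$fold_up
    p
  }
  fam <- sprintf("F%02d", seq_len(config$n_shared_families))
  structure(list(ortho = ortho,
                 true_pairs = data.frame(type_s1 = fam, type_s2 = fam,
                                         stringsAsFactors = FALSE),
                 program_s1 = program(marker_sets$s1),
                 program_s2 = program(marker_sets$s2),
                 split_s1 = w1, split_s2 = w2,
                 marker_sets = marker_sets,
                 config = config),
            class = "SimTruth")
}

# NB draws at dispersion alpha (variance mu + alpha mu^2); Poisson at 0
rnb <- function(n, mu, alpha) {
  if (alpha > 0) stats::rnbinom(n, mu = mu, size = 1 / alpha)
  else stats::rpois(n, mu)
}

sim_counts_one_species <- function(config, truth, side, seed) {
  program <- if (side == "s1") truth$program_s1 else truth$program_s2
  split_w <- if (side == "s1") truth$split_s1 else truth$split_s2
  og_genes <- if (side == "s1") truth$ortho$genes_s1 else truth$ortho$genes_s2
  genes <- unlist(og_genes, use.names = FALSE)
  og_of_gene <- rep.int(seq_along(og_genes), lengths(og_genes))
  types <- colnames(program)

  # per-gene x per-type expected counts at library factor 1
  mu_gene <- program[og_of_gene, , drop = FALSE] * split_w[genes]
  rownames(mu_gene) <- genes
  # dedicated mitochondrial genes absorb mito_frac_mean of expression mass
  if (config$n_mito_genes > 0L && config$mito_frac_mean > 0) {
    mito_ids <- sprintf("MT-%s-%02d", side, seq_len(config$n_mito_genes))
    mito_total <- config$mito_frac_mean / (1 - config$mito_frac_mean) *
      colSums(mu_gene)
    mu_mito <- matrix(rep(mito_total / config$n_mito_genes,
                          each = config$n_mito_genes),
                      nrow = config$n_mito_genes,
                      dimnames = list(mito_ids, types))
    mu_gene <- rbind(mu_gene, mu_mito)
  }

  n_cells <- length(types) * config$cells_per_type
  barcodes <- sprintf("%s_bc%05d", side, seq_len(n_cells))
  cell_type <- rep(types, each = config$cells_per_type)
  blocks <- vector("list", length(types))
  withr::with_seed(seed, {
    L <- stats::rlnorm(n_cells, 0, config$libsize_sigma)
    for (ti in seq_along(types)) {
      idx <- which(cell_type == types[ti])
      mu <- outer(mu_gene[, types[ti]], L[idx])
      x <- rnb(length(mu), mu, config$nb_dispersion)
      blocks[[ti]] <- Matrix::Matrix(matrix(x, nrow = nrow(mu_gene)),
                                     sparse = TRUE)
    }
  })
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(rownames(mu_gene), barcodes)
  list(matrix = count_matrix(counts, species = side),
       annotation = data.frame(cell_id = barcodes, cluster_label = cell_type,
                               species = side, stringsAsFactors = FALSE))
}

#' Simulate UMI count matrices for both species
#'
#' Per cell, a library-size factor `L ~ LogNormal(0, libsize_sigma)` scales
#' all expected means; the count of gene `g` in a cell of type `t` is drawn
#' from a negative binomial with mean `L * mu_{t,g}` and dispersion
#' `nb_dispersion`.
#'
#' @param config a [sim_config()].
#' @param truth a `SimTruth` from [simulate_programs()].
#' @return list with `s1`, `s2` (`CountMatrix`) and `ann_s1`, `ann_s2`
#'   (per-cell annotation data frames).
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "SimTruth"))
  r1 <- sim_counts_one_species(config, truth, "s1", config$seed + 2L)
  r2 <- sim_counts_one_species(config, truth, "s2", config$seed + 3L)
  list(s1 = r1$matrix, s2 = r2$matrix,
       ann_s1 = r1$annotation, ann_s2 = r2$annotation)
}

#' Simulate a complete paired-species atlas
#'
#' Convenience wrapper running [simulate_gene_forest()],
#' [simulate_programs()] and [simulate_counts()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with elements `s1`, `s2`, `ann_s1`, `ann_s2`, `ortho` and
#'   `truth`.
#' @export
simulate_atlas <- function(config = sim_config()) {
  ortho <- simulate_gene_forest(config)
  truth <- simulate_programs(config, ortho)
  counts <- simulate_counts(config, truth)
  c(counts, list(ortho = ortho, truth = truth))
}

#' Write a simulated atlas to disk as plain-text fixtures
#'
#' Writes 10x-style MTX triplets (one directory per species), annotation
#' TSVs, the orthology table in OrthoFinder `Orthogroups.tsv` dialect, and
#' ground-truth tables.
#'
#' @param sim output of [simulate_atlas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$s1, file.path(dir, "s1"), dialect = "mtx_triplet")
  write_count_matrix(sim$s2, file.path(dir, "s2"), dialect = "mtx_triplet")
  write_annotation(sim$ann_s1, file.path(dir, "annotation_s1.tsv"))
  write_annotation(sim$ann_s2, file.path(dir, "annotation_s2.tsv"))
  write_orthology(sim$ortho, file.path(dir, "orthogroups.tsv"))
  utils::write.table(sim$truth$true_pairs,
                     file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (side in c("s1", "s2")) {
    p <- sim$truth[[paste0("program_", side)]]
    utils::write.table(data.frame(orthogroup = rownames(p), p,
                                  check.names = FALSE),
                       file.path(dir, sprintf("truth_program_%s.tsv", side)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
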