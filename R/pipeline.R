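#' Default pipeline run configuration
#'
#' A nested, YAML-serializable configuration covering every stage: simulate
#' (or load) the two atlases, QC both, collapse to meta-genes, select HVGs,
#' compute specificity indices, detect markers, and compare cell types
#' across species. `config_write()` / `config_read()` round-trip it through
#' YAML unchanged.
#'
#' When `input` is non-NULL the simulator is skipped and the pipeline reads
#' `matrix_s1`/`matrix_s2` (MTX triplet directories), `annotation_s1`/
#' `annotation_s2` (TSV) and `orthology` (Orthogroups.tsv dialect) instead.
#'
#' @param sim named list of [sim_config()] overrides.
#' @param input optional named list of input paths (see above).
#' @param qc named list of [qc_params()] arguments applied to both species;
#'   `mito_pattern` (default `"^MT-"`) derives the mitochondrial gene list.
#' @param k_hvg highly variable meta-genes per species (union is used).
#' @param gene_set optional character vector of orthogroup indices to
#'   restrict the comparison (e.g. TF orthogroups).
#' @param run_markers whether to run one-vs-rest marker detection.
#' @param n_boot,scales bootstrap settings for [compare_celltypes()].
#' @param seed master seed; the simulator and bootstrap derive their streams
#'   from it.
#' @return a `RunConfig` list.
#' @export
run_config <- function(sim = list(), input = NULL,
                       qc = list(min_cells_per_gene = 5L,
                                 min_umis_per_cell = 200L,
                                 max_mito_frac = 0.10,
                                 mito_pattern = "^MT-"),
                       k_hvg = 3000L, gene_set = NULL,
                       run_markers = TRUE,
                       n_boot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                       seed = 1L) {
  cfg <- list(sim = sim, input = input, qc = qc, k_hvg = k_hvg,
              gene_set = gene_set, run_markers = run_markers,
              n_boot = n_boot, scales = scales, seed = as.integer(seed))
  structure(cfg, class = "RunConfig")
}

#' @rdname run_config
#' @param config a `RunConfig`.
#' @param path YAML file.
#' @export
config_write <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

write_specificity <- function(sp, path) {
  utils::write.table(
    data.frame(gene = rownames(sp$values), sp$values, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(cluster_sizes = as.list(sp$cluster_sizes), N = sp$N,
         normalization_tag = sp$normalization_tag,
         n_masked = sum(sp$masked)),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the full cross-species homology pipeline
#'
#' Executes simulate (or load) -> QC -> meta-gene collapse -> HVG selection
#' -> specificity -> markers -> cross-species comparison in a fixed order,
#' writing every artifact plus a manifest (MD5 of each file, parameters,
#' seed, package version) under `out_dir`. Reruns with an identical
#' configuration reproduce identical artifacts and manifests.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with `result` (the [homology_result()]),
#'   `specificity` (per species), `metrics` (from
#'   [evaluate_against_truth()], simulated runs only), `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_write(config, file.path(out_dir, "config.yaml"))

  simulated <- is.null(config$input)
  if (simulated) {
    sc <- do.call(sim_config, c(config$sim,
                                if (is.null(config$sim$seed))
                                  list(seed = config$seed)))
    atlas <- stage_run("simulate", simulate_atlas(sc))
    truth <- atlas$truth
  } else {
    atlas <- stage_run("load", list(
      s1 = read_count_matrix(config$input$matrix_s1, "mtx_triplet", "s1"),
      s2 = read_count_matrix(config$input$matrix_s2, "mtx_triplet", "s2"),
      ann_s1 = read_annotation(config$input$annotation_s1),
      ann_s2 = read_annotation(config$input$annotation_s2),
      ortho = read_orthology(config$input$orthology)))
    truth <- NULL
  }

  qc_args <- config$qc
  mito_pattern <- qc_args$mito_pattern %||% "^MT-"
  qc_args$mito_pattern <- NULL
  qcres <- list()
  for (side in c("s1", "s2")) {
    params <- do.call(qc_params, c(
      qc_args, list(mito_gene_ids = grep(mito_pattern,
                                         gene_ids(atlas[[side]]),
                                         value = TRUE))))
    qcres[[side]] <- stage_run(paste0("qc_", side),
                               qc_filter(atlas[[side]], params))
    write_qc_report(qcres[[side]]$report,
                    file.path(out_dir, sprintf("qc_%s.json", side)))
  }

  meta <- list()
  for (side in c("s1", "s2")) {
    meta[[side]] <- stage_run(paste0("collapse_", side),
                              collapse_to_metagenes(qcres[[side]]$matrix,
                                                    atlas$ortho, side))
    write_count_matrix(meta[[side]],
                       file.path(out_dir, sprintf("metagenes_%s", side)))
  }

  hvg_union <- stage_run("hvg", {
    sets <- lapply(meta, function(m) {
      norm <- normalize_counts(m)
      select_hvgs(norm, k = min(config$k_hvg, nrow(norm)))
    })
    sort(unique(unlist(sets)))
  })

  spl <- list()
  for (side in c("s1", "s2")) {
    ann <- atlas[[paste0("ann_", side)]]
    ann <- ann[ann$cell_id %in% cell_ids(meta[[side]]), , drop = FALSE]
    spl[[side]] <- stage_run(paste0("specificity_", side),
                             compute_specificity(meta[[side]], ann,
                                                 gene_subset = hvg_union))
    write_specificity(spl[[side]],
                      file.path(out_dir, sprintf("specificity_%s.tsv", side)))
  }

  if (isTRUE(config$run_markers)) {
    for (side in c("s1", "s2")) {
      ann <- atlas[[paste0("ann_", side)]]
      norm <- normalize_counts(meta[[side]])
      mk <- stage_run(paste0("markers_", side),
                      find_all_markers(norm, ann))
      utils::write.table(mk, file.path(out_dir,
                                       sprintf("markers_%s.tsv", side)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  result <- stage_run("compare",
                      compare_celltypes(spl$s1, spl$s2,
                                        gene_set = config$gene_set,
                                        species_names = c("s1", "s2"),
                                        n_boot = config$n_boot,
                                        scales = config$scales,
                                        seed = config$seed))
  write_homology(result, file.path(out_dir, "homology"))

  metrics <- NULL
  if (simulated) {
    metrics <- stage_run("evaluate", evaluate_against_truth(result, truth))
    jsonlite::write_json(metrics, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- write_manifest(out_dir, config)
  invisible(list(result = result, specificity = spl, metrics = metrics,
                 manifest = manifest, truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# manifest: sorted MD5 of every artifact plus parameters and versions
write_manifest <- function(out_dir, config) {
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE, full.names = FALSE),
    "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(package = "orthocell",
                   version = as.character(utils::packageVersion("orthocell")),
                   seed = config$seed,
                   parameters = unclass(config),
                   files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Score a homology result against simulation ground truth
#'
#' @param result a [homology_result()] from a simulated run.
#' @param truth the `SimTruth` of the simulated atlas.
#' @return list with `recovery` (matched and total as integers, plus rate),
#'   `precision` of the RBH pairs, `mean_r_true_pairs`, `mean_r_non_pairs`,
#'   `min_r_true_pairs`, `private_cross_matches` (private-to-private RBH
#'   pairs with r at or above the weakest true pair), and a per-true-pair
#'   table with correlation and, when available, the BP/AU support of the
#'   pair's two-leaf clade.
#' @export
evaluate_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "HomologyResult"), inherits(truth, "SimTruth"))
  tp <- truth$true_pairs
  if (!all(tp$type_s1 %in% rownames(result$corr)) ||
      !all(tp$type_s2 %in% colnames(result$corr)))
    stop("truth/atlas mismatch: true-pair cell types absent from result")

  rbh_key <- paste(result$rbh_pairs$type_s1, result$rbh_pairs$type_s2)
  true_key <- paste(tp$type_s1, tp$type_s2)
  matched <- sum(true_key %in% rbh_key)
  r_true <- result$corr[cbind(tp$type_s1, tp$type_s2)]
  non <- result$corr
  non[cbind(tp$type_s1, tp$type_s2)] <- NA
  r_non <- non[is.finite(non)]

  priv1 <- setdiff(colnames(truth$program_s1), tp$type_s1)
  priv2 <- setdiff(colnames(truth$program_s2), tp$type_s2)
  pc <- result$rbh_pairs$type_s1 %in% priv1 &
    result$rbh_pairs$type_s2 %in% priv2 &
    result$rbh_pairs$r >= min(r_true)

  pair_table <- data.frame(tp, r = r_true, bp = NA_real_, au = NA_real_)
  if (!is.null(result$support)) {
    clade <- vapply(seq_len(nrow(tp)), function(i)
      paste(sort(c(paste0("s1|", tp$type_s1[i]),
                   paste0("s2|", tp$type_s2[i]))), collapse = ","), "")
    hit <- match(clade, result$support$clade)
    pair_table$bp <- result$support$bp[hit]
    pair_table$au <- result$support$au[hit]
  }
  list(recovery = list(matched = as.integer(matched),
                       total = as.integer(nrow(tp)),
                       rate = matched / nrow(tp)),
       precision = if (nrow(result$rbh_pairs))
         sum(rbh_key %in% true_key) / nrow(result$rbh_pairs) else NA_real_,
       mean_r_true_pairs = mean(r_true),
       mean_r_non_pairs = mean(r_non),
       min_r_true_pairs = min(r_true),
       private_cross_matches = as.integer(sum(pc)),
       pair_table = pair_table)
}
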