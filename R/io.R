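#' Read a UMI count matrix
#'
#' Supports the 10x-style MatrixMarket triplet (a directory containing
#' `matrix.mtx`, `genes.tsv`, `barcodes.tsv`) and a dense TSV with gene IDs
#' in the first column and cell IDs in the header.
#'
#' @param path directory (`mtx_triplet`) or file (`dense_tsv`).
#' @param dialect input format.
#' @param species species tag to attach.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, dialect = c("mtx_triplet", "dense_tsv"),
                              species = "s1") {
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    barcodes <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, barcodes))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    gid <- utils::read.delim(genes, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
    cid <- utils::read.delim(barcodes, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(gid) || ncol(m) != length(cid))
      stop(sprintf(
        "dimension mismatch: matrix is %d x %d but %d genes and %d barcodes listed",
        nrow(m), ncol(m), length(gid), length(cid)))
    dimnames(m) <- list(gid, cid)
    count_matrix(m, species = species)
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gid <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in dense TSV")
    rownames(m) <- gid
    count_matrix(m, species = species)
  }
}

# MatrixMarket "coordinate integer" writer (column-major, 1-based).
# Matrix::writeMM only emits the "real" field, so the 10x integer dialect
# is written directly.
write_mm_integer <- function(m, path) {
  m <- methods::as(m, "CsparseMatrix")
  i <- m@i + 1L
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)),
               sprintf("%d %d %d", i, j, as.integer(m@x))),
             con = con)
  invisible(path)
}

#' Write a UMI count matrix
#'
#' @param x a [count_matrix()].
#' @param path output directory (`mtx_triplet`) or file (`dense_tsv`).
#' @param dialect output format; the MTX triplet uses the MatrixMarket
#'   "coordinate integer" field.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path,
                               dialect = c("mtx_triplet", "dense_tsv")) {
  stopifnot(inherits(x, "CountMatrix"))
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_mm_integer(x$counts, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(x), file.path(path, "genes.tsv"))
    writeLines(cell_ids(x), file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = gene_ids(x), as.matrix(x$counts),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell annotation table
#'
#' @param path TSV with at least `cell_id` and `cluster_label` columns.
#' @return data frame with non-empty cluster labels.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_id", "cluster_label")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(ann$cluster_label)) || anyNA(ann$cluster_label))
    stop("empty cluster labels in annotation")
  if (anyDuplicated(ann$cell_id))
    stop("duplicate cell_id in annotation")
  ann
}

#' @rdname read_annotation
#' @param ann annotation data frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-species orthology table
#'
#' Parses an OrthoFinder `Orthogroups.tsv`-style file: one orthogroup per
#' row, one column per species holding a comma-space-separated gene list.
#' Rows with an empty gene list in either species are dropped (their count
#' is reported in a message and in `attr(, "n_dropped")`); orthogroups are
#' renumbered contiguously `1..n`.
#'
#' @param path the TSV file.
#' @param species_cols length-2 character (column names) or integer
#'   (positions) picking the two species columns; default columns 2 and 3.
#' @return an [ortho_map()].
#' @export
read_orthology <- function(path, species_cols = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (is.null(species_cols)) {
    if (ncol(tab) < 3L) stop("orthology table needs an ID column plus two species columns")
    species_cols <- names(tab)[2:3]
  }
  if (is.character(species_cols)) {
    miss <- setdiff(species_cols, names(tab))
    if (length(miss))
      stop("unknown species column: ", paste(miss, collapse = ", "))
  }
  if (length(species_cols) != 2L) stop("exactly two species columns required")
  split_genes <- function(x) {
    x[is.na(x)] <- ""
    lapply(strsplit(x, ",[[:space:]]*"), function(g) g[nzchar(g)])
  }
  g1 <- split_genes(tab[[species_cols[1]]])
  g2 <- split_genes(tab[[species_cols[2]]])
  keep <- lengths(g1) > 0L & lengths(g2) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " orthogroup row(s) empty in one species dropped")
  if (!any(keep)) stop("no orthogroup has genes in both species")
  om <- ortho_map(g1[keep], g2[keep],
                  species = as.character(species_cols), provenance = path)
  attr(om, "n_dropped") <- n_dropped
  om
}

#' @rdname read_orthology
#' @param ortho an [ortho_map()].
#' @export
write_orthology <- function(ortho, path) {
  tab <- data.frame(
    Orthogroup = sprintf("OG%07d", seq_along(ortho$genes_s1)),
    s1 = vapply(ortho$genes_s1, paste, "", collapse = ", "),
    s2 = vapply(ortho$genes_s2, paste, "", collapse = ", "))
  names(tab)[2:3] <- ortho$species
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
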