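#' Write a dataset as MTX + TSV triplet
#'
#' CellRanger-style layout: `matrix.mtx` (genes x cells), `genes.tsv`
#' (gene_id, mito, coding), `barcodes.tsv`, plus `labels.tsv`
#' (cell_id, label) when true labels are present.
#'
#' @param dataset a `synthetic_dataset` (or count matrix with flags).
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset_mtx <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- get_counts(dataset)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  flags <- get_gene_flags(dataset) %||%
    data.frame(gene_id = rownames(m), mito = FALSE, coding = NA)
  utils::write.table(flags, file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (inherits(dataset, "synthetic_dataset")) {
    utils::write.table(
      data.frame(cell_id = names(dataset$true_labels),
                 label = dataset$true_labels),
      file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `labels.tsv`.
#' @return a `synthetic_dataset`-shaped list (without a config) when
#'   labels are present, otherwise a count matrix with a `gene_flags`
#'   attribute.
#' @export
read_dataset_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  flags <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(flags$gene_id, barcodes)
  labels_path <- file.path(dir, "labels.tsv")
  if (file.exists(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    labels <- lab$label
    names(labels) <- lab$cell_id
    structure(list(counts = m, true_labels = labels, gene_flags = flags,
                   config = NULL),
              class = "synthetic_dataset")
  } else {
    attr(m, "gene_flags") <- flags
    m
  }
}

#' Write clustering results as a long TSV
#'
#' Columns: `dataset_id`, `pipeline_id`, `cell_id`, `label`.
#'
#' @param results list of `clustering_result`s.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_clusterings_tsv <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (!is.null(r$error) || !length(r$labels)) return(NULL)
    data.frame(dataset_id = r$dataset_id, pipeline_id = r$pipeline_id,
               cell_id = names(r$labels), label = unname(r$labels),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
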