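#' Read an expression matrix with batch labels
#'
#' Loads a cells x genes expression matrix from disk. Two layouts are
#' supported:
#'
#' * `format = "mtx"`: a MatrixMarket coordinate file (genes x cells or
#'   cells x genes, see `mtx_orientation`) plus sidecar text files
#'   `<prefix>_genes.tsv` and `<prefix>_cells.tsv` (one name per line;
#'   the cells file may have additional label columns with a header).
#' * `format = "csv"` / `"tsv"`: a dense table whose header row holds
#'   gene names and whose first column holds cell IDs; label columns
#'   named in `batch_key` / `cell_type_key` may be embedded.
#'
#' Per-cell labels are taken from an embedded column (dense formats), or
#' from `labels_path` — a TSV with a `cell_id` column plus the label
#' columns. Every cell must resolve a batch label.
#'
#' @param path file path (for `mtx`, the `.mtx` file; sidecars are found
#'   by replacing the `.mtx` suffix).
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param batch_key name of the batch-label column.
#' @param cell_type_key optional name of the cell-type column.
#' @param labels_path optional TSV of per-cell labels (`cell_id` column
#'   required); mandatory for `mtx` unless the cells sidecar embeds labels.
#' @param mtx_orientation `"genes_x_cells"` (CellRanger convention,
#'   default) or `"cells_x_genes"`.
#' @return A [labeled_expression()].
#' @export
load_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            batch_key = "batch", cell_type_key = NULL,
                            labels_path = NULL,
                            mtx_orientation = c("genes_x_cells", "cells_x_genes")) {
  format <- match.arg(format)
  mtx_orientation <- match.arg(mtx_orientation)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    prefix <- sub("\\.mtx$", "", path)
    genes_f <- paste0(prefix, "_genes.tsv")
    cells_f <- paste0(prefix, "_cells.tsv")
    if (!file.exists(genes_f) || !file.exists(cells_f))
      stop("sidecar files not found: ", genes_f, " / ", cells_f)
    gene_names <- data.table::fread(genes_f, header = FALSE, sep = "\t")[[1]]
    cells_tab <- data.table::fread(cells_f, header = TRUE, sep = "\t")
    if (!"cell_id" %in% names(cells_tab)) {
      # headerless single-column fallback: first row was consumed as header
      cells_tab <- data.table::fread(cells_f, header = FALSE, sep = "\t")
      names(cells_tab)[1] <- "cell_id"
    }
    cell_ids <- as.character(cells_tab$cell_id)
    if (mtx_orientation == "genes_x_cells") m <- t(m)
    if (nrow(m) != length(cell_ids)) stop("matrix rows != number of cells in sidecar")
    if (ncol(m) != length(gene_names)) stop("matrix cols != number of genes in sidecar")
    lab <- cells_tab
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- data.table::fread(path, header = TRUE, sep = sep)
    cell_ids <- as.character(tab[[1]])
    tab <- tab[, -1, with = FALSE]
    label_cols <- intersect(c(batch_key, cell_type_key), names(tab))
    lab <- data.table::data.table(cell_id = cell_ids)
    for (cn in label_cols) lab[[cn]] <- as.character(tab[[cn]])
    gene_cols <- setdiff(names(tab), label_cols)
    m <- as.matrix(tab[, gene_cols, with = FALSE])
    gene_names <- gene_cols
  }

  if (!is.null(labels_path)) {
    ext <- data.table::fread(labels_path, header = TRUE, sep = "\t")
    if (!"cell_id" %in% names(ext)) stop("labels file must have a cell_id column")
    idx <- match(cell_ids, as.character(ext$cell_id))
    if (anyNA(idx)) stop("labels file does not cover all cells")
    for (cn in setdiff(names(ext), "cell_id")) lab[[cn]] <- as.character(ext[[cn]])[idx]
  }

  if (!batch_key %in% names(lab))
    stop("batch label column '", batch_key, "' not found")
  batch <- as.character(lab[[batch_key]])
  if (anyNA(batch) || any(batch == ""))
    stop("missing batch label for at least one cell")
  ctl <- NULL
  if (!is.null(cell_type_key) && cell_type_key %in% names(lab))
    ctl <- as.character(lab[[cell_type_key]])

  labeled_expression(m, gene_names, cell_ids, batch, ctl)
}

#' Write an expression matrix
#'
#' Mirrors [load_expression()]: writes either a dense CSV/TSV (first
#' column `cell_id`, then the batch / cell-type label columns, then one
#' column per gene) or a MatrixMarket file with `_genes.tsv` /
#' `_cells.tsv` sidecars. Gene and cell ordering is preserved.
#'
#' @param x a [labeled_expression()].
#' @param path output path (`.mtx` for `format = "mtx"`).
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(x$matrix), sparse = TRUE), path)
    prefix <- sub("\\.mtx$", "", path)
    writeLines(x$gene_names, paste0(prefix, "_genes.tsv"))
    cells <- data.table::data.table(cell_id = x$cell_ids, batch = x$batch_labels)
    if (!is.null(x$cell_type_labels)) cells$cell_type <- x$cell_type_labels
    data.table::fwrite(cells, paste0(prefix, "_cells.tsv"), sep = "\t")
  } else {
    tab <- data.table::data.table(cell_id = x$cell_ids, batch = x$batch_labels)
    if (!is.null(x$cell_type_labels)) tab$cell_type <- x$cell_type_labels
    tab <- cbind(tab, data.table::as.data.table(x$matrix))
    data.table::fwrite(tab, path, sep = if (format == "csv") "," else "\t")
  }
  invisible(path)
}
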