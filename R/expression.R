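#' Labeled expression matrix
#'
#' The central data container: a cells x genes expression matrix together
#' with per-cell batch labels and optional per-cell cell-type labels.
#' Rows are cells, columns are genes; values must be finite and
#' non-negative (counts or normalized expression).
#'
#' @param matrix numeric matrix, cells x genes, non-negative and finite.
#' @param gene_names character vector of unique gene names (columns).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param batch_labels character/factor vector of per-cell batch labels.
#' @param cell_type_labels optional character/factor vector of per-cell
#'   cell-type labels, or `NULL`.
#' @param hvg_names optional character vector recording a selected
#'   highly-variable-gene list (set by [select_hvgs()]).
#'
#' @return An object of class `labeled_expression`: a list with elements
#'   `matrix`, `gene_names`, `cell_ids`, `batch_labels`,
#'   `cell_type_labels`, `hvg_names`.
#' @export
labeled_expression <- function(matrix, gene_names, cell_ids, batch_labels,
                               cell_type_labels = NULL, hvg_names = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  batch_labels <- as.character(batch_labels)
  if (!is.null(cell_type_labels)) cell_type_labels <- as.character(cell_type_labels)

  if (nrow(matrix) != length(cell_ids))
    stop("row count (", nrow(matrix), ") != number of cell ids (", length(cell_ids), ")")
  if (nrow(matrix) != length(batch_labels))
    stop("row count != number of batch labels")
  if (ncol(matrix) != length(gene_names))
    stop("column count (", ncol(matrix), ") != number of gene names (", length(gene_names), ")")
  if (!is.null(cell_type_labels) && length(cell_type_labels) != nrow(matrix))
    stop("cell_type_labels length != number of cells")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  if (any(!is.finite(matrix))) stop("expression matrix contains non-finite values")
  if (any(matrix < 0)) stop("expression matrix contains negative values")
  if (anyNA(batch_labels)) stop("missing batch labels")

  rownames(matrix) <- cell_ids
  colnames(matrix) <- gene_names
  structure(
    list(matrix = matrix, gene_names = gene_names, cell_ids = cell_ids,
         batch_labels = batch_labels, cell_type_labels = cell_type_labels,
         hvg_names = hvg_names),
    class = "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat("labeled_expression: ", nrow(x$matrix), " cells x ", ncol(x$matrix),
      " genes\n", sep = "")
  cat("  batches: ", paste(names(table(x$batch_labels)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$cell_type_labels))
    cat("  cell types: ", length(unique(x$cell_type_labels)), "\n", sep = "")
  if (!is.null(x$hvg_names))
    cat("  HVGs recorded: ", length(x$hvg_names), "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_expression <- function(x) dim(x$matrix)

# Subset cells (i) and/or genes (j) keeping metadata aligned.
subset_expression <- function(x, i = NULL, j = NULL) {
  m <- x$matrix
  cid <- x$cell_ids; bl <- x$batch_labels; ctl <- x$cell_type_labels
  gn <- x$gene_names
  if (!is.null(i)) {
    m <- m[i, , drop = FALSE]; cid <- cid[i]; bl <- bl[i]
    if (!is.null(ctl)) ctl <- ctl[i]
  }
  if (!is.null(j)) {
    m <- m[, j, drop = FALSE]; gn <- gn[j]
  }
  hv <- x$hvg_names
  if (!is.null(hv)) hv <- intersect(hv, gn)
  labeled_expression(m, gn, cid, bl, ctl, hvg_names = hv)
}

# Number of distinct batches; correction entry points need >= 2.
n_batches <- function(x) length(unique(x$batch_labels))

assert_multi_batch <- function(x) {
  if (n_batches(x) < 2)
    stop("at least 2 distinct batches are required for batch correction")
  invisible(x)
}
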