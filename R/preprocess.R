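#' Remove genes by name prefix
#'
#' Drops spike-in and mitochondrial genes whose names start with any of
#' the given prefixes. Matching is case-sensitive and anchored at the
#' first character, so `"MT-"` removes `MT-CO1` but not `MTCH1`, and
#' `"mt-"` (murine convention) is listed separately from `"MT-"`.
#'
#' @param x a [labeled_expression()].
#' @param prefixes character vector of prefixes to remove.
#' @return `x` with matching genes dropped; cells unchanged.
#' @export
filter_gene_prefixes <- function(x, prefixes = c("ERCC", "MT-", "mt-")) {
  drop <- rep(FALSE, length(x$gene_names))
  for (p in prefixes)
    drop <- drop | startsWith(x$gene_names, p)
  if (all(drop)) stop("all genes removed by prefix filter")
  if (!any(drop)) return(x)
  subset_expression(x, j = which(!drop))
}

#' Remove cells expressing too few genes
#'
#' @param x a [labeled_expression()].
#' @param min_genes keep a cell only if it has a nonzero value for at
#'   least this many genes.
#' @return `x` with low-complexity cells dropped; genes unchanged.
#' @export
filter_cells_min_genes <- function(x, min_genes = 600) {
  if (min_genes < 0) stop("min_genes must be >= 0")
  n_expressed <- rowSums(x$matrix > 0)
  keep <- n_expressed >= min_genes
  if (!any(keep)) stop("all cells removed by min_genes filter")
  if (all(keep)) return(x)
  subset_expression(x, i = which(keep))
}

#' Remove genes expressed in too few cells
#'
#' @param x a [labeled_expression()].
#' @param min_cells keep a gene only if it is nonzero in at least this
#'   many cells.
#' @return `x` with rarely-detected genes dropped; cells unchanged.
#' @export
filter_genes_min_cells <- function(x, min_cells = 3) {
  if (min_cells < 0) stop("min_cells must be >= 0")
  n_cells <- colSums(x$matrix > 0)
  keep <- n_cells >= min_cells
  if (!any(keep)) stop("all genes removed by min_cells filter")
  if (all(keep)) return(x)
  subset_expression(x, j = which(keep))
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion: per gene, dispersion =
#' variance / mean; genes are binned into `n_bins` equal-width bins
#' by mean expression and each gene's dispersion is z-scored against its
#' bin's dispersion mean and standard deviation. The top `n_top` genes
#' by normalized dispersion are retained (all genes if fewer are
#' available). Selection is computed on the concatenated multi-batch
#' matrix in a single pass.
#'
#' @param x a [labeled_expression()].
#' @param n_top number of genes to keep (default 2000).
#' @param n_bins number of mean-expression bins (default 20).
#' @return `x` restricted to the selected genes, with `hvg_names` set.
#' @export
select_hvgs <- function(x, n_top = 2000, n_bins = 20) {
  if (n_top < 1) stop("n_top must be >= 1")
  g <- ncol(x$matrix)
  if (g < 2) stop("need at least 2 genes for HVG selection")
  mu <- colMeans(x$matrix)
  v <- apply(x$matrix, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-width bins on the mean; degenerate bins get sd of 1 so a
  # lone gene in a bin is neither favored nor excluded
  n_bins <- max(1L, min(n_bins, g))
  bin <- if (length(unique(mu)) > 1) cut(mu, breaks = n_bins, include.lowest = TRUE)
         else factor(rep(1L, g))
  bm <- tapply(disp, bin, mean)
  bs <- tapply(disp, bin, stats::sd)
  # single-gene bins have no spread: score those genes against their own
  # dispersion (normalized dispersion 1) rather than dropping them
  single <- is.na(bs)
  bs[single] <- bm[single]
  bm[single] <- 0
  bs[is.na(bs) | bs == 0] <- 1
  norm_disp <- (disp - bm[bin]) / bs[bin]
  keep <- order(norm_disp, decreasing = TRUE)[seq_len(min(n_top, g))]
  keep <- sort(keep)  # preserve original gene order
  out <- subset_expression(x, j = keep)
  out$hvg_names <- out$gene_names
  out
}

#' Depth-normalize and log-transform
#'
#' Scales every cell so its total expression equals `target_sum`, then
#' applies the natural-log `log1p` transform elementwise. Must be
#' applied exactly once in the pipeline (the transform is not
#' idempotent).
#'
#' @param x a [labeled_expression()] of non-negative values with no
#'   all-zero cell.
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return transformed [labeled_expression()].
#' @export
normalize_and_log <- function(x, target_sum = 1e4) {
  if (target_sum <= 0) stop("target_sum must be positive")
  totals <- rowSums(x$matrix)
  if (any(totals == 0))
    stop("cell(s) with zero total expression; filter cells first")
  m <- log1p(x$matrix * (target_sum / totals))
  labeled_expression(m, x$gene_names, x$cell_ids, x$batch_labels,
                     x$cell_type_labels, hvg_names = x$hvg_names)
}

#' PCA embedding
#'
#' Principal-component scores of the gene-centered matrix (genes are
#' mean-centered, not scaled), computed by SVD. Component variances are
#' non-increasing and scores are mutually orthogonal.
#'
#' @param x a [labeled_expression()] with finite values.
#' @param n_components number of components; must satisfy
#'   `n_components <= min(cells - 1, genes)`.
#' @return An `embedding` object: list with `coords` (cells x
#'   `n_components` score matrix, rows named by cell ID), `cell_index`
#'   (cell IDs), `n_components`, `sdev` (component standard deviations).
#' @export
pca_embed <- function(x, n_components = 50) {
  n <- nrow(x$matrix); g <- ncol(x$matrix)
  if (n_components < 1 || n_components > min(n - 1, g))
    stop("n_components must be in [1, min(cells - 1, genes)]")
  centered <- sweep(x$matrix, 2, colMeans(x$matrix))
  sv <- svd(centered, nu = n_components, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- x$cell_ids
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(
    list(coords = coords, cell_index = x$cell_ids,
         n_components = n_components,
         sdev = sv$d[seq_len(n_components)] / sqrt(max(1, n - 1))),
    class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding: ", nrow(x$coords), " cells x ", x$n_components,
      " components\n", sep = "")
  invisible(x)
}

#' Standard preprocessing pipeline
#'
#' Applies, in order: gene-prefix filter, cell filter (min expressed
#' genes), gene filter (min expressing cells), HVG selection,
#' depth normalization, log1p, PCA. Returns both the processed
#' HVG-space expression and its PCA embedding.
#'
#' @param x a [labeled_expression()] of raw counts.
#' @param prefixes gene-name prefixes to drop.
#' @param min_genes,min_cells filtering thresholds.
#' @param n_hvgs number of highly variable genes.
#' @param target_sum per-cell total for depth normalization.
#' @param n_pcs number of principal components.
#' @return list with `expr` (normalized-log HVG-space
#'   [labeled_expression()]) and `embedding` (its PCA [pca_embed()]).
#' @export
preprocess <- function(x, prefixes = c("ERCC", "MT-", "mt-"),
                       min_genes = 600, min_cells = 3, n_hvgs = 2000,
                       target_sum = 1e4, n_pcs = 50) {
  x <- filter_gene_prefixes(x, prefixes)
  x <- filter_cells_min_genes(x, min_genes)
  x <- filter_genes_min_cells(x, min_cells)
  x <- select_hvgs(x, n_hvgs)
  x <- normalize_and_log(x, target_sum)
  n_pcs <- min(n_pcs, nrow(x$matrix) - 1, ncol(x$matrix))
  emb <- pca_embed(x, n_pcs)
  list(expr = x, embedding = emb)
}
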