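# Reduce a wide representation (e.g. 2000 HVGs) to a PCA space before
# distance-based scoring; metrics on very high-dimensional vectors are
# noisy. Pass-through for matrices already narrow enough.
metric_representation <- function(coords, n_pcs = 20, use_raw = FALSE) {
  coords <- as.matrix(coords)
  if (use_raw || ncol(coords) <= n_pcs) return(coords)
  centered <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centered, nu = n_pcs, nv = 0)
  sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
}

# Restrict scoring to cell types present in every batch ("common" types).
common_type_mask <- function(batch_labels, type_labels) {
  tab <- table(type_labels, batch_labels)
  common <- rownames(tab)[rowSums(tab > 0) == ncol(tab)]
  type_labels %in% common
}

check_labeling <- function(labels, what) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop(what, " labeling has a single class; scores are undefined")
  labels
}

#' Silhouette-based mixing and purity scores
#'
#' Average silhouette width (ASW, Euclidean distance) of the batch and
#' cell-type labelings over the given representation. Reported with the
#' plotting convention that higher is better for both axes: batch
#' mixing as `1 - ASW_batch`, cell-type purity as `ASW_celltype`.
#'
#' @param coords numeric matrix (cells x features): an embedding or a
#'   corrected expression matrix (reduced to `n_pcs` PCs unless
#'   `use_raw`).
#' @param batch_labels,type_labels per-cell labelings, >= 2 classes each.
#' @param restrict_common restrict to cell types present in every batch?
#' @param n_pcs,use_raw see [metric_representation()].
#' @return named numeric vector `c(asw_batch_complement, asw_celltype)`.
#' @export
asw_scores <- function(coords, batch_labels, type_labels,
                       restrict_common = TRUE, n_pcs = 20, use_raw = FALSE) {
  batch_labels <- check_labeling(batch_labels, "batch")
  type_labels <- check_labeling(type_labels, "cell-type")
  if (restrict_common) {
    keep <- common_type_mask(batch_labels, type_labels)
    coords <- coords[keep, , drop = FALSE]
    batch_labels <- check_labeling(batch_labels[keep], "batch")
    type_labels <- check_labeling(type_labels[keep], "cell-type")
  }
  rep_ <- metric_representation(coords, n_pcs, use_raw)
  d <- stats::dist(rep_)
  asw_of <- function(lab) {
    sil <- cluster::silhouette(as.integer(factor(lab)), d)
    mean(sil[, "sil_width"])
  }
  c(asw_batch_complement = 1 - asw_of(batch_labels),
    asw_celltype = asw_of(type_labels))
}

#' ARI-based mixing and purity scores
#'
#' Clusters the representation with k-means (k = number of distinct
#' cell types, 10 restarts) and scores the clustering against both
#' labelings with the adjusted Rand index. Reported as
#' `1 - ARI_batch` (batch mixing) and `ARI_celltype` (purity).
#'
#' @inheritParams asw_scores
#' @param seed seed for the k-means restarts.
#' @return named numeric vector `c(ari_batch_complement, ari_celltype)`.
#' @export
ari_scores <- function(coords, batch_labels, type_labels,
                       restrict_common = TRUE, n_pcs = 20, use_raw = FALSE,
                       seed = 1) {
  batch_labels <- check_labeling(batch_labels, "batch")
  type_labels <- check_labeling(type_labels, "cell-type")
  if (restrict_common) {
    keep <- common_type_mask(batch_labels, type_labels)
    coords <- coords[keep, , drop = FALSE]
    batch_labels <- check_labeling(batch_labels[keep], "batch")
    type_labels <- check_labeling(type_labels[keep], "cell-type")
  }
  rep_ <- metric_representation(coords, n_pcs, use_raw)
  k <- length(unique(type_labels))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cl <- stats::kmeans(rep_, centers = k, nstart = 10, iter.max = 50)$cluster
  c(ari_batch_complement = 1 - mclust::adjustedRandIndex(cl, batch_labels),
    ari_celltype = mclust::adjustedRandIndex(cl, type_labels))
}

# Per-cell inverse Simpson's index over a Gaussian-kernel neighborhood
# calibrated to `perplexity` (binary search on the kernel precision,
# the t-SNE/LISI convention). Returns raw per-cell LISI in [1, K].
lisi_per_cell <- function(coords, labels, perplexity = 30) {
  n <- nrow(coords)
  labels <- as.integer(factor(labels))
  K <- max(labels)
  n_neigh <- min(n - 1, as.integer(3 * perplexity))
  d2 <- cross_sqdist(coords, coords)
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i][seq_len(n_neigh)]
    di <- d2[i, ord]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    p <- w / sum(w)
    props <- vapply(seq_len(K), function(k) sum(p[labels[ord] == k]), numeric(1))
    out[i] <- 1 / sum(props^2)
  }
  out
}

#' LISI-based mixing and purity scores
#'
#' Local inverse Simpson's index: the effective number of label classes
#' in each cell's perplexity-calibrated Gaussian neighborhood, averaged
#' over cells. Raw LISI lies in `[1, K]`; scores are rescaled to
#' `[0, 1]` via `(L - 1) / (K - 1)` so that the reported complement
#' `1 - cLISI` is meaningful. Returns `1 - cLISI_scaled` (cell-type
#' purity, higher = purer) and `iLISI_scaled` (batch mixing, higher =
#' better mixed).
#'
#' @inheritParams asw_scores
#' @param perplexity neighborhood size parameter (default 30); requires
#'   `cells > 3 * perplexity`.
#' @return named numeric vector `c(clisi_complement, ilisi)`.
#' @export
lisi_scores <- function(coords, batch_labels, type_labels, perplexity = 30,
                        restrict_common = TRUE, n_pcs = 20, use_raw = FALSE) {
  batch_labels <- check_labeling(batch_labels, "batch")
  type_labels <- check_labeling(type_labels, "cell-type")
  if (restrict_common) {
    keep <- common_type_mask(batch_labels, type_labels)
    coords <- coords[keep, , drop = FALSE]
    batch_labels <- check_labeling(batch_labels[keep], "batch")
    type_labels <- check_labeling(type_labels[keep], "cell-type")
  }
  if (nrow(coords) <= 3 * perplexity)
    stop("need more than 3 * perplexity cells for LISI")
  rep_ <- metric_representation(coords, n_pcs, use_raw)
  scale01 <- function(raw, K) if (K > 1) (mean(raw) - 1) / (K - 1) else 0
  Kb <- length(unique(batch_labels))
  Kt <- length(unique(type_labels))
  ilisi <- scale01(lisi_per_cell(rep_, batch_labels, perplexity), Kb)
  clisi <- scale01(lisi_per_cell(rep_, type_labels, perplexity), Kt)
  c(clisi_complement = 1 - clisi, ilisi = ilisi)
}

#' Full mixing/purity score report
#'
#' Convenience wrapper computing all six scores of the evaluation
#' convention: `1 - ASW_batch`, `ASW_celltype`, `1 - ARI_batch`,
#' `ARI_celltype`, `1 - cLISI` and `iLISI` (all oriented so that higher
#' is better).
#'
#' @inheritParams asw_scores
#' @inheritParams lisi_scores
#' @return named list of the six scores plus `restricted_to_common_types`.
#' @export
score_report <- function(coords, batch_labels, type_labels,
                         restrict_common = TRUE, perplexity = 30,
                         n_pcs = 20, use_raw = FALSE) {
  asw <- asw_scores(coords, batch_labels, type_labels, restrict_common,
                    n_pcs, use_raw)
  ari <- ari_scores(coords, batch_labels, type_labels, restrict_common,
                    n_pcs, use_raw)
  lisi <- lisi_scores(coords, batch_labels, type_labels, perplexity,
                      restrict_common, n_pcs, use_raw)
  as.list(c(asw, ari, lisi,
            restricted_to_common_types = as.numeric(restrict_common)))
}
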