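# Pairwise squared Euclidean distances between rows of a and rows of b.
cross_sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# Indices of the k nearest rows of `to` for each row of `from` (ties
# broken by index order, stable).
knn_indices <- function(from, to, k) {
  d <- cross_sqdist(from, to)
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Mutual nearest neighbors between two batches (single round)
#'
#' A pair (a, b) is kept iff b is among the `k_mnn` nearest neighbors of
#' a within batch B (Euclidean distance in the embedding) and a is among
#' the `k_mnn` nearest of b within batch A. Mutuality is symmetric, so
#' swapping the batches yields the same pair set.
#'
#' @param emb_a,emb_b numeric matrices of embedding coordinates (rows =
#'   cells of one batch), with cell IDs as row names.
#' @param k_mnn neighborhood size; must be `<= min(nrow(emb_a), nrow(emb_b))`.
#' @return data.frame with columns `cell_a`, `cell_b` (one row per
#'   mutual pair).
#' @export
find_mnn_pairs <- function(emb_a, emb_b, k_mnn = 20) {
  if (nrow(emb_a) == 0 || nrow(emb_b) == 0) stop("empty batch")
  if (is.null(rownames(emb_a)) || is.null(rownames(emb_b)))
    stop("embeddings must carry cell IDs as row names")
  k <- min(k_mnn, nrow(emb_a), nrow(emb_b))
  d <- cross_sqdist(emb_a, emb_b)
  nn_ab <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))       # a -> b
  nn_ba <- t(apply(d, 2, function(r) order(r)[seq_len(k)]))       # b -> a
  in_ab <- matrix(FALSE, nrow(emb_a), nrow(emb_b))
  in_ab[cbind(rep(seq_len(nrow(emb_a)), k), as.vector(nn_ab))] <- TRUE
  in_ba <- matrix(FALSE, nrow(emb_a), nrow(emb_b))
  in_ba[cbind(as.vector(nn_ba), rep(seq_len(nrow(emb_b)), k))] <- TRUE
  idx <- which(in_ab & in_ba, arr.ind = TRUE)
  data.frame(cell_a = rownames(emb_a)[idx[, 1]],
             cell_b = rownames(emb_b)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Multi-round MNN pairing across all batches
#'
#' Repeats the MNN search `n_rounds` times. In each round, at most
#' `sample_cap` not-yet-paired cells are uniformly sampled per batch,
#' MNN pairs are found for every pair of batches among the sampled
#' cells, and all newly paired cells are removed from the pool before
#' the next round. Repeated rounds with removal increase the diversity
#' of paired cells; the cap bounds the cost per round. Rounds that
#' yield no new pair stop the search early.
#'
#' @param embedding an [pca_embed()] embedding (or any object with
#'   `coords` + `cell_index`).
#' @param batch_labels per-cell batch labels aligned with the embedding.
#' @param k_mnn mutual-neighborhood size (default 20).
#' @param n_rounds maximum number of rounds (default 3).
#' @param sample_cap per-batch per-round sampling cap (default 3000).
#' @return A `pair_set`: data.frame with columns `cell_a`, `cell_b`,
#'   `batch_a`, `batch_b`, `round`. No pair joins two cells of the same
#'   batch, and each cell appears in pairs from at most one round.
#' @export
multi_round_mnn <- function(embedding, batch_labels, k_mnn = 20,
                            n_rounds = 3, sample_cap = 3000) {
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  coords <- embedding$coords
  ids <- embedding$cell_index
  batch_labels <- as.character(batch_labels)
  if (length(batch_labels) != nrow(coords))
    stop("batch_labels length != number of embedded cells")
  batches <- unique(batch_labels)
  if (length(batches) < 2) stop("need >= 2 batches")

  unpaired <- stats::setNames(rep(TRUE, length(ids)), ids)
  out <- list()
  for (r in seq_len(n_rounds)) {
    sampled <- list()
    for (b in batches) {
      pool <- which(batch_labels == b & unpaired[ids])
      if (length(pool) == 0) next
      take <- min(sample_cap, length(pool))
      sampled[[b]] <- if (take < length(pool)) sort(sample(pool, take)) else pool
    }
    bs <- names(sampled)
    if (length(bs) < 2) break
    new_pairs <- list()
    for (i in seq_len(length(bs) - 1)) for (j in seq(i + 1, length(bs))) {
      ia <- sampled[[bs[i]]]; ib <- sampled[[bs[j]]]
      ea <- coords[ia, , drop = FALSE]; rownames(ea) <- ids[ia]
      eb <- coords[ib, , drop = FALSE]; rownames(eb) <- ids[ib]
      p <- find_mnn_pairs(ea, eb, k_mnn)
      if (nrow(p) > 0) {
        p$batch_a <- bs[i]; p$batch_b <- bs[j]
        new_pairs[[length(new_pairs) + 1]] <- p
      }
    }
    if (length(new_pairs) == 0) break
    np <- do.call(rbind, new_pairs)
    np$round <- r
    out[[r]] <- np
    unpaired[unique(c(np$cell_a, np$cell_b))] <- FALSE
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_a = character(), cell_b = character(),
               batch_a = character(), batch_b = character(),
               round = integer(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Within-batch k-nearest neighbors
#'
#' For every cell, the `k` nearest cells of the same batch (Euclidean
#' distance in the embedding), self excluded. A cell in a singleton
#' batch gets an empty neighbor list.
#'
#' @inheritParams multi_round_mnn
#' @param k neighborhood size (default 10).
#' @return A `within_batch_knn`: list with `k` and `neighbors`, a named
#'   list mapping each cell ID to its ordered same-batch neighbor IDs.
#' @export
within_batch_knn <- function(embedding, batch_labels, k = 10) {
  coords <- embedding$coords
  ids <- embedding$cell_index
  batch_labels <- as.character(batch_labels)
  neighbors <- stats::setNames(vector("list", length(ids)), ids)
  for (b in unique(batch_labels)) {
    idx <- which(batch_labels == b)
    if (length(idx) == 1) { neighbors[[ids[idx]]] <- character(0); next }
    kk <- min(k, length(idx) - 1)
    d <- cross_sqdist(coords[idx, , drop = FALSE], coords[idx, , drop = FALSE])
    diag(d) <- Inf
    for (ii in seq_along(idx)) {
      nb <- order(d[ii, ])[seq_len(kk)]
      neighbors[[ids[idx[ii]]]] <- ids[idx[nb]]
    }
  }
  structure(list(k = k, neighbors = neighbors), class = "within_batch_knn")
}

#' Build the cross-batch similar-cell connected graph
#'
#' Nodes are all cells appearing in MNN pairs; every MNN pair is an
#' edge. Closed-loop and transmitting connections arise automatically
#' as connected components of that edge set. If `use_weak = TRUE`, the
#' transmissibility condition is loosened: for same-batch cells A, A'
#' that are mutual members of each other's within-batch k-NN lists,
#' with MNN edges A-B and A'-C where B and C lie in two further,
#' distinct batches, a `weak` edge B-C is added. Components confined to
#' a single batch are discarded.
#'
#' @param pairs a `pair_set` from [multi_round_mnn()].
#' @param knn a [within_batch_knn()] (required when `use_weak = TRUE`).
#' @param use_weak add weak-transmitting edges?
#' @param mutual_knn require A and A' to appear in each other's k-NN
#'   lists (default) rather than one-directional membership.
#' @param batch_of named character vector mapping cell ID -> batch
#'   (needed to place weak-edge endpoints; inferred from `pairs` if
#'   omitted).
#' @return A `cohort_graph`: list with `components` (list of cell-ID
#'   character vectors), `edges` (data.frame `from`, `to`, `kind`),
#'   `batches_present` (list of per-component batch sets), `membership`
#'   (named component index per cell), `batch_of`.
#' @export
build_cohort_graph <- function(pairs, knn = NULL, use_weak = FALSE,
                               mutual_knn = TRUE, batch_of = NULL) {
  if (nrow(pairs) == 0) stop("pair set is empty")
  if (is.null(batch_of))
    batch_of <- c(stats::setNames(pairs$batch_a, pairs$cell_a),
                  stats::setNames(pairs$batch_b, pairs$cell_b))
  batch_of <- batch_of[!duplicated(names(batch_of))]

  edges <- data.frame(from = pairs$cell_a, to = pairs$cell_b,
                      kind = "mnn", stringsAsFactors = FALSE)

  if (use_weak) {
    if (is.null(knn)) stop("use_weak = TRUE requires a within_batch_knn")
    # MNN partners of each anchor cell, grouped by anchor
    partners <- split(c(pairs$cell_b, pairs$cell_a),
                      c(pairs$cell_a, pairs$cell_b))
    anchors <- intersect(names(partners), names(knn$neighbors))
    weak <- list()
    for (a in anchors) {
      for (a2 in intersect(knn$neighbors[[a]], anchors)) {
        if (a2 <= a) next  # each unordered anchor pair once
        if (mutual_knn && !(a %in% knn$neighbors[[a2]])) next
        for (b in partners[[a]]) for (cc in partners[[a2]]) {
          if (b == cc) next
          # B and C must lie in two distinct batches, both different
          # from the anchors' batch (three-batch configuration)
          if (batch_of[[b]] == batch_of[[cc]]) next
          if (batch_of[[b]] == batch_of[[a]] || batch_of[[cc]] == batch_of[[a]]) next
          weak[[length(weak) + 1]] <- c(b, cc)
        }
      }
    }
    if (length(weak)) {
      w <- unique(do.call(rbind, weak))
      edges <- rbind(edges, data.frame(from = w[, 1], to = w[, 2],
                                       kind = "weak", stringsAsFactors = FALSE))
    }
  }

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  cells <- names(membership)
  comp_cells <- split(cells, membership)
  batches_present <- lapply(comp_cells, function(cs) unique(unname(batch_of[cs])))
  keep <- vapply(batches_present, function(b) length(b) >= 2, logical(1))
  comp_cells <- unname(comp_cells[keep])
  batches_present <- unname(batches_present[keep])
  membership <- stats::setNames(rep(NA_integer_, length(cells)), cells)
  for (i in seq_along(comp_cells)) membership[comp_cells[[i]]] <- i
  membership <- membership[!is.na(membership)]

  structure(
    list(components = comp_cells, edges = edges,
         batches_present = batches_present, membership = membership,
         batch_of = batch_of),
    class = "cohort_graph")
}

#' @export
print.cohort_graph <- function(x, ...) {
  cat("cohort_graph: ", length(x$components), " components, ",
      nrow(x$edges), " edges (", sum(x$edges$kind == "weak"),
      " weak), ", length(x$membership), " cells\n", sep = "")
  invisible(x)
}

#' Cohort sampler over a cohort graph
#'
#' Returns a function that draws cohorts of similar cells: each draw
#' picks a component (with probability proportional to component size,
#' so well-supported components contribute more training pairs) and,
#' within it, one uniformly sampled cell per batch present in that
#' component.
#'
#' @param graph a [build_cohort_graph()] result with >= 1 component.
#' @return `function(n = 1)` returning a list of `n` cohorts; each
#'   cohort is a named character vector (names = batches, values = cell
#'   IDs) with >= 2 entries and all batches distinct.
#' @export
extract_cohort_sampler <- function(graph) {
  if (length(graph$components) < 1) stop("graph has no multi-batch component")
  by_batch <- lapply(graph$components, function(cs)
    split(cs, unname(graph$batch_of[cs])))
  sizes <- vapply(graph$components, length, numeric(1))
  probs <- sizes / sum(sizes)
  function(n = 1) {
    comp_idx <- sample.int(length(by_batch), n, replace = TRUE, prob = probs)
    lapply(comp_idx, function(ci) {
      groups <- by_batch[[ci]]
      vapply(groups, function(cs)
        if (length(cs) == 1) cs else sample(cs, 1), character(1))
    })
  }
}
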