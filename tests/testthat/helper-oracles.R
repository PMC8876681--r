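# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# Mutual k-NN pairs by exhaustive distance tables and simple loops.
oracle_mnn <- function(emb_a, emb_b, k) {
  k <- min(k, nrow(emb_a), nrow(emb_b))
  na <- nrow(emb_a); nb <- nrow(emb_b)
  d <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt(sum((emb_a[i, ] - emb_b[j, ])^2))
  knn_of_a <- lapply(seq_len(na), function(i) order(d[i, ])[seq_len(k)])
  knn_of_b <- lapply(seq_len(nb), function(j) order(d[, j])[seq_len(k)])
  pairs <- character(0)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (j %in% knn_of_a[[i]] && i %in% knn_of_b[[j]])
      pairs <- c(pairs, paste(rownames(emb_a)[i], rownames(emb_b)[j], sep = "|"))
  }
  sort(pairs)
}

# Connected components of an undirected edge list via union-find.
oracle_components <- function(from, to) {
  nodes <- unique(c(from, to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in seq_along(from)) {
    ra <- find(from[e]); rb <- find(to[e])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  comps <- split(nodes, roots)
  # canonical form: sorted members, components sorted by first member
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

canonical_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Per-cell silhouette by direct definition.
oracle_asw <- function(coords, labels) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (length(own) == 0) { sil[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

# ARI from the contingency-table closed form.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Raw per-cell LISI by direct definition: Gaussian kernel over the
# 3*perplexity nearest neighbors, precision calibrated by bisection to
# entropy log(perplexity), then inverse Simpson of label proportions.
oracle_lisi <- function(coords, labels, perplexity) {
  n <- nrow(coords)
  labels <- as.character(labels)
  classes <- unique(labels)
  d <- as.matrix(stats::dist(coords))^2
  m <- min(n - 1, 3 * perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(d[i, ]), i)[seq_len(m)]
    di <- d[i, nb]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-beta * di); p <- p / sum(p)
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - log(perplexity)) < 1e-5) break
      if (h > log(perplexity)) {
        lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else 2 * beta
      } else {
        hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p <- exp(-beta * di); p <- p / sum(p)
    simpson <- 0
    for (cl in classes) simpson <- simpson + sum(p[labels[nb] == cl])^2
    out[i] <- 1 / simpson
  }
  out
}

# Toy labeled_expression builder.
toy_expr <- function(m, batches, types = NULL, genes = NULL, cells = NULL) {
  m <- as.matrix(m)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(nrow(m)))
  labeled_expression(m, genes, cells, batches, types)
}

# Embedding wrapper around raw coordinates for graph-level tests.
toy_embedding <- function(coords, ids = NULL) {
  coords <- as.matrix(coords)
  if (is.null(ids)) ids <- paste0("c", seq_len(nrow(coords)))
  rownames(coords) <- ids
  structure(list(coords = coords, cell_index = ids,
                 n_components = ncol(coords),
                 sdev = rep(1, ncol(coords))),
            class = "embedding")
}

# Numerical gradient of a scalar function by central differences.
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
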