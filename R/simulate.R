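#' Simulation configuration
#'
#' Parameters of the multi-batch negative-binomial count simulator.
#' Genes receive a log-normal base mean; a `de_fraction` subset of
#' genes gets multiplicative differential-expression factors per cell
#' type; every gene gets a multiplicative log-normal batch factor with
#' log-scale `batch_effect_scale` per batch; per-cell library sizes are
#' gamma distributed and counts are negative binomial.
#'
#' @param n_batches number of batches (>= 2).
#' @param cells_per_batch integer vector (recycled) of cells per batch.
#' @param n_genes number of genes.
#' @param n_types number of cell types.
#' @param type_proportions matrix (`n_batches` x `n_types`) of per-batch
#'   type proportions, each row summing to 1; zeros give non-overlapping
#'   designs. Default: uniform across types in every batch.
#' @param de_fraction fraction of genes carrying type-specific factors.
#' @param de_strength log-scale of the DE factors (default 1).
#' @param batch_effect_scale log-scale of the per-gene batch factors;
#'   0 means no batch effect.
#' @param library_size_mean,library_size_shape gamma library-size model.
#' @param nb_dispersion negative-binomial `size` (inverse overdispersion).
#' @param seed RNG seed; the simulation is deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_batches = 2, cells_per_batch = 500, n_genes = 500,
                       n_types = 3, type_proportions = NULL,
                       de_fraction = 0.2, de_strength = 1,
                       batch_effect_scale = 0.5,
                       library_size_mean = 5000, library_size_shape = 10,
                       nb_dispersion = 10, seed = 1) {
  stopifnot(n_batches >= 2, n_genes >= 1, n_types >= 1,
            de_fraction >= 0, de_fraction <= 1, batch_effect_scale >= 0,
            library_size_mean > 0, library_size_shape > 0, nb_dispersion > 0)
  cells_per_batch <- rep_len(as.integer(cells_per_batch), n_batches)
  if (is.null(type_proportions))
    type_proportions <- matrix(1 / n_types, n_batches, n_types)
  type_proportions <- as.matrix(type_proportions)
  if (!all(dim(type_proportions) == c(n_batches, n_types)))
    stop("type_proportions must be n_batches x n_types")
  if (any(type_proportions < 0) ||
      any(abs(rowSums(type_proportions) - 1) > 1e-8))
    stop("each batch's type proportions must be non-negative and sum to 1")
  structure(list(n_batches = n_batches, cells_per_batch = cells_per_batch,
                 n_genes = n_genes, n_types = n_types,
                 type_proportions = type_proportions,
                 de_fraction = de_fraction, de_strength = de_strength,
                 batch_effect_scale = batch_effect_scale,
                 library_size_mean = library_size_mean,
                 library_size_shape = library_size_shape,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labeled multi-batch count matrix
#'
#' Generates cells x genes negative-binomial counts with known cell
#' types and an injected multiplicative batch effect, so every pipeline
#' stage can be exercised and scored against ground truth without
#' external data.
#'
#' @param config a [sim_config()].
#' @return a [labeled_expression()] with batch and true cell-type labels.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  base_mean <- exp(stats::rnorm(g, mean = 1, sd = 1))     # log-normal base

  # type-specific multiplicative DE factors on a random gene subset
  n_de <- round(config$de_fraction * g)
  type_factor <- matrix(1, config$n_types, g)
  for (ty in seq_len(config$n_types)) {
    de_genes <- sample.int(g, n_de)
    type_factor[ty, de_genes] <-
      exp(stats::rnorm(n_de, mean = 0, sd = config$de_strength))
  }

  # per-batch multiplicative log-normal factors on all genes
  batch_factor <- matrix(
    exp(stats::rnorm(config$n_batches * g, mean = 0,
                     sd = config$batch_effect_scale)),
    config$n_batches, g)

  n_cells <- sum(config$cells_per_batch)
  counts <- matrix(0L, n_cells, g)
  batch_lab <- character(n_cells); type_lab <- character(n_cells)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  at <- 0L
  for (b in seq_len(config$n_batches)) {
    nb <- config$cells_per_batch[b]
    types <- sample.int(config$n_types, nb, replace = TRUE,
                        prob = config$type_proportions[b, ])
    lib <- stats::rgamma(nb, shape = config$library_size_shape,
                         rate = config$library_size_shape / config$library_size_mean)
    for (i in seq_len(nb)) {
      mu_gene <- base_mean * type_factor[types[i], ] * batch_factor[b, ]
      mu <- mu_gene / sum(mu_gene) * lib[i]
      counts[at + i, ] <- stats::rnbinom(g, mu = mu, size = config$nb_dispersion)
    }
    batch_lab[at + seq_len(nb)] <- paste0("batch", b)
    type_lab[at + seq_len(nb)] <- paste0("type", types)
    at <- at + nb
  }
  labeled_expression(counts, sprintf("gene_%04d", seq_len(g)), cell_ids,
                     batch_lab, type_lab)
}
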