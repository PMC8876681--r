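#' End-to-end batch correction
#'
#' Runs the full pipeline: preprocessing (filters, HVG selection,
#' normalization, log transform, PCA), multi-round MNN pairing,
#' cross-batch similar-cell connected-graph construction, intermediate-
#' batch synthesis under the chosen pattern, WGAN-GP training, and
#' correction of every cell (cells outside any cohort included).
#'
#' @param x a [labeled_expression()] of raw counts with >= 2 batches.
#' @param pattern synthesis pattern: `"mean"`, `"max"` or `"min"`.
#' @param min_genes,min_cells,n_hvgs,target_sum,n_pcs preprocessing
#'   parameters, see [preprocess()].
#' @param k_mnn,k_within,n_rounds,sample_cap,use_weak graph parameters,
#'   see [multi_round_mnn()] and [build_cohort_graph()].
#' @param n_draws cohort draws for the training set (default
#'   `5 * n_components`), see [build_training_set()].
#' @param gen_hidden,crit_hidden hidden widths of generator and critic.
#' @param config a [train_config()]; its `seed` drives all randomness
#'   (subsampling, cohort draws, initialization, minibatches).
#' @param verbose print progress?
#' @return list with `corrected` (corrected HVG-space expression),
#'   `raw_hvg` (pre-correction normalized-log HVG expression),
#'   `embedding` (pre-correction PCA), `pairs`, `graph`, `model`
#'   (trained `imgg_generator`).
#' @export
imgg_correct <- function(x, pattern = c("mean", "max", "min"),
                         min_genes = 600, min_cells = 3, n_hvgs = 2000,
                         target_sum = 1e4, n_pcs = 50,
                         k_mnn = 20, k_within = 10, n_rounds = 3,
                         sample_cap = 3000, use_weak = TRUE,
                         n_draws = NULL,
                         gen_hidden = c(1024, 1024),
                         crit_hidden = c(256, 256),
                         config = train_config(), verbose = FALSE) {
  pattern <- match.arg(pattern)
  assert_multi_batch(x)
  say <- function(...) if (verbose) message(...)

  say("preprocessing ...")
  pp <- preprocess(x, min_genes = min_genes, min_cells = min_cells,
                   n_hvgs = n_hvgs, target_sum = target_sum, n_pcs = n_pcs)
  expr <- pp$expr; emb <- pp$embedding
  assert_multi_batch(expr)

  set.seed(config$seed)
  say("multi-round MNN search ...")
  pairs <- multi_round_mnn(emb, expr$batch_labels, k_mnn = k_mnn,
                           n_rounds = n_rounds, sample_cap = sample_cap)
  if (nrow(pairs) == 0) stop("no MNN pairs found; batches may be disjoint")
  knn <- if (use_weak) within_batch_knn(emb, expr$batch_labels, k = k_within)
         else NULL
  graph <- build_cohort_graph(pairs, knn, use_weak = use_weak)

  say("building training set (", length(graph$components), " components) ...")
  train_set <- build_training_set(graph, expr, pattern, n_draws = n_draws)

  say("training WGAN-GP ...")
  model <- train_imgg(train_set,
                      gen_spec = generator_spec(train_set$n_genes, gen_hidden),
                      crit_spec = critic_spec(train_set$n_genes, crit_hidden),
                      config = config, verbose = verbose)

  say("correcting all cells ...")
  corrected <- correct_expression(expr, model)

  list(corrected = corrected, raw_hvg = expr, embedding = emb,
       pairs = pairs, graph = graph, model = model)
}
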