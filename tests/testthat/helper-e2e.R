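# Shared end-to-end correction run on simulated two-batch data with a
# strong injected batch effect. Computed once per test session and
# reused by the tests that score it from different angles.
.e2e_cache <- new.env(parent = emptyenv())

e2e_run <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  x <- simulate_expression(sim_config(
    n_batches = 2, cells_per_batch = 1000, n_genes = 500, n_types = 3,
    batch_effect_scale = 1.0, seed = 2024))
  res <- imgg_correct(
    x, "mean", min_genes = 20, min_cells = 3, n_hvgs = 300, n_pcs = 30,
    gen_hidden = c(256, 256), crit_hidden = c(128, 128),
    config = train_config(epochs = 100, batch_size = 256, seed = 11))
  .e2e_cache$res <- res
  res
}
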