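#' Synthesize an intermediate-batch target for one cohort
#'
#' The intermediate batch is built per cohort of similar cells:
#' elementwise `Mean` (equalizes expression differences between
#' batches), `Max` (combines the strong points of different protocols),
#' or `Min` across the cohort members' expression vectors.
#'
#' @param cohort_exprs numeric matrix, one row per cohort member
#'   (>= 2 rows), columns = genes; or a list of equal-length vectors.
#' @param pattern one of `"mean"`, `"max"`, `"min"` (case-insensitive).
#' @return numeric vector: the synthesis target in gene space.
#' @export
synthesize_target <- function(cohort_exprs, pattern = c("mean", "max", "min")) {
  pattern <- tolower(match.arg(tolower(pattern)[1], c("mean", "max", "min")))
  if (is.list(cohort_exprs)) {
    lens <- lengths(cohort_exprs)
    if (length(unique(lens)) != 1) stop("cohort vectors have unequal lengths")
    cohort_exprs <- do.call(rbind, cohort_exprs)
  }
  if (nrow(cohort_exprs) < 2) stop("a cohort needs >= 2 members")
  switch(pattern,
         mean = colMeans(cohort_exprs),
         max = apply(cohort_exprs, 2, max),
         min = apply(cohort_exprs, 2, min))
}

#' Build the GAN training set from cohort draws
#'
#' Draws `n_draws` cohorts via [extract_cohort_sampler()], maps each
#' cohort into HVG expression space, and builds (source, target) rows:
#' each member's expression vector becomes a source paired with the
#' cohort's synthesis target, so one draw of a c-member cohort
#' contributes c rows sharing one target.
#'
#' @param graph a [build_cohort_graph()] result.
#' @param hvg_expr the normalized-log HVG-space [labeled_expression()];
#'   every graph cell must be present.
#' @param pattern synthesis pattern, see [synthesize_target()].
#' @param n_draws number of cohort draws; default `5 *
#'   length(graph$components)`, capped so the training set stays below
#'   `max_rows` rows.
#' @param max_rows hard cap on training rows (default 100000).
#' @return A `training_pairs`: list with `sources` and `targets`
#'   (equal-size numeric matrices, rows = training examples), `n_genes`,
#'   `pattern`, `draw` (integer draw index per row) and `cell_id`
#'   (source cell per row).
#' @export
build_training_set <- function(graph, hvg_expr,
                               pattern = c("mean", "max", "min"),
                               n_draws = NULL, max_rows = 100000) {
  pattern <- match.arg(pattern)
  cells <- names(graph$membership)
  missing <- setdiff(cells, hvg_expr$cell_ids)
  if (length(missing))
    stop("graph cell(s) missing from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (is.null(n_draws)) n_draws <- 5L * length(graph$components)
  # rows per draw ~ number of batches in the sampled component
  est_batches <- mean(vapply(graph$batches_present, length, numeric(1)))
  n_draws <- min(n_draws, max(1L, floor(max_rows / max(2, est_batches))))

  sampler <- extract_cohort_sampler(graph)
  cohorts <- sampler(n_draws)
  m <- hvg_expr$matrix
  n_genes <- ncol(m)

  rows <- sum(lengths(cohorts))
  sources <- matrix(0, rows, n_genes)
  targets <- matrix(0, rows, n_genes)
  draw <- integer(rows); cid <- character(rows)
  at <- 0L
  for (d in seq_along(cohorts)) {
    members <- cohorts[[d]]
    ex <- m[members, , drop = FALSE]
    tgt <- synthesize_target(ex, pattern)
    idx <- at + seq_along(members)
    sources[idx, ] <- ex
    targets[idx, ] <- matrix(tgt, length(members), n_genes, byrow = TRUE)
    draw[idx] <- d
    cid[idx] <- unname(members)
    at <- at + length(members)
  }
  structure(
    list(sources = sources, targets = targets, n_genes = n_genes,
         pattern = pattern, draw = draw, cell_id = cid),
    class = "training_pairs")
}

#' @export
print.training_pairs <- function(x, ...) {
  cat("training_pairs: ", nrow(x$sources), " rows x ", x$n_genes,
      " genes (pattern = ", x$pattern, ", ",
      length(unique(x$draw)), " draws)\n", sep = "")
  invisible(x)
}
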