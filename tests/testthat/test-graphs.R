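test_that("find_mnn_pairs matches hand-derived toys and is symmetric", {
  # single cell per batch: always mutual
  a <- toy_embedding(matrix(c(0, 0), 1), "a1")
  b <- toy_embedding(matrix(c(5, 5), 1), "b1")
  p <- find_mnn_pairs(a$coords, b$coords, 1)
  expect_equal(nrow(p), 1L)

  # A at (0,0),(10,10); B at (0,1),(20,20); k=1 -> only (0,0)-(0,1)
  ea <- toy_embedding(rbind(c(0, 0), c(10, 10)), c("a1", "a2"))
  eb <- toy_embedding(rbind(c(0, 1), c(20, 20)), c("b1", "b2"))
  p <- find_mnn_pairs(ea$coords, eb$coords, 1)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$cell_a, p$cell_b), c("a1", "b1"))

  # symmetry: swapping batches yields the same pair set
  p_sw <- find_mnn_pairs(eb$coords, ea$coords, 1)
  expect_setequal(paste(p$cell_a, p$cell_b),
                  paste(p_sw$cell_b, p_sw$cell_a))

  expect_error(find_mnn_pairs(ea$coords[0, , drop = FALSE], eb$coords, 1),
               "empty")
})

test_that("MNN pairs match the brute-force mutual-kNN oracle on random instances", {
  set.seed(101)
  for (rep in 1:10) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1); k <- sample(1:5, 1)
    ea <- toy_embedding(matrix(rnorm(na * 3), na), paste0("a", 1:na))
    eb <- toy_embedding(matrix(rnorm(nb * 3), nb), paste0("b", 1:nb))
    got <- find_mnn_pairs(ea$coords, eb$coords, k)
    expect_equal(sort(paste(got$cell_a, got$cell_b, sep = "|")),
                 oracle_mnn(ea$coords, eb$coords, k))
  }
})

test_that("multi-round MNN removes paired cells and annotates rounds", {
  # 2 batches x 4 cells in well-separated duos: with k=1 every duo is a
  # mutual pair, so round 1 pairs all cells and round 2 stops early
  a_pts <- rbind(c(0, 0), c(100, 0), c(0, 100), c(300, 300))
  b_pts <- rbind(c(1, 0), c(101, 0), c(1, 100), c(301, 300))
  emb <- toy_embedding(rbind(a_pts, b_pts),
                       c(paste0("a", 1:4), paste0("b", 1:4)))
  batches <- rep(c("A", "B"), each = 4)
  set.seed(1)
  ps <- multi_round_mnn(emb, batches, k_mnn = 1, n_rounds = 3, sample_cap = 4)
  expect_setequal(paste(ps$cell_a, ps$cell_b),
                  paste(paste0("a", 1:4), paste0("b", 1:4)))
  expect_true(all(ps$round == 1))
  expect_true(all(ps$batch_a != ps$batch_b))

  # n_rounds = 1 equals a single find_mnn_pairs call on the full batches
  set.seed(2)
  one <- multi_round_mnn(emb, batches, k_mnn = 2, n_rounds = 1,
                         sample_cap = 10)
  base <- find_mnn_pairs(emb$coords[1:4, ], emb$coords[5:8, ], 2)
  expect_setequal(paste(one$cell_a, one$cell_b),
                  paste(base$cell_a, base$cell_b))

  # sample_cap = 1: each round samples one unpaired cell per batch, the
  # cross pair is always mutual, so 3 rounds give 3 disjoint pairs
  set.seed(3)
  capped <- multi_round_mnn(emb, batches, k_mnn = 1, n_rounds = 3,
                            sample_cap = 1)
  expect_equal(unname(table(capped$round)), c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(c(capped$cell_a, capped$cell_b)), 0L)

  # determinism under a fixed seed
  set.seed(77)
  p1 <- multi_round_mnn(emb, batches, 2, n_rounds = 2, sample_cap = 3)
  set.seed(77)
  p2 <- multi_round_mnn(emb, batches, 2, n_rounds = 2, sample_cap = 3)
  expect_identical(p1, p2)

  expect_error(multi_round_mnn(emb, batches, 1, n_rounds = 0), "n_rounds")
})

test_that("within-batch kNN excludes self and other batches", {
  # 3 collinear cells at 0, 1, 10 in one batch, k=1
  emb <- toy_embedding(matrix(c(0, 1, 10, 5), ncol = 1),
                       c("c0", "c1", "c2", "other"))
  batches <- c("A", "A", "A", "B")
  knn <- within_batch_knn(emb, batches, k = 1)
  expect_equal(knn$neighbors[["c0"]], "c1")
  expect_equal(knn$neighbors[["c1"]], "c0")
  expect_equal(knn$neighbors[["c2"]], "c1")
  # singleton batch gets an empty list
  expect_length(knn$neighbors[["other"]], 0)

  # k >= batch size - 1 -> all other same-batch cells, never cross-batch
  knn2 <- within_batch_knn(emb, batches, k = 10)
  expect_setequal(knn2$neighbors[["c0"]], c("c1", "c2"))
  expect_false("other" %in% unlist(knn2$neighbors[c("c0", "c1", "c2")]))
})

test_that("closed-loop and transmitting structures form single components", {
  # closed loop: triangle across 3 batches
  tri <- data.frame(cell_a = c("A1", "A2", "A1"), cell_b = c("A2", "A3", "A3"),
                    batch_a = c("b1", "b2", "b1"), batch_b = c("b2", "b3", "b3"),
                    round = 1L)
  class(tri) <- c("pair_set", "data.frame")
  g <- build_cohort_graph(tri)
  expect_length(g$components, 1)
  expect_setequal(g$components[[1]], c("A1", "A2", "A3"))

  # transmitting: chain without the closing edge is still one component
  chain <- tri[1:2, ]
  g2 <- build_cohort_graph(chain)
  expect_length(g2$components, 1)
  expect_setequal(g2$components[[1]], c("A1", "A2", "A3"))
})

test_that("weak transmitting edges merge components only when enabled", {
  # A, A2 mutual 1-NNs in batch 1; MNN edges A-B (batch 2), A2-C (batch 3)
  pairs <- data.frame(cell_a = c("A", "A2"), cell_b = c("B", "C"),
                      batch_a = c("b1", "b1"), batch_b = c("b2", "b3"),
                      round = 1L)
  class(pairs) <- c("pair_set", "data.frame")
  emb <- toy_embedding(rbind(c(0, 0), c(0, 1), c(5, 5), c(9, 9)),
                       c("A", "A2", "B", "C"))
  knn <- within_batch_knn(emb, c("b1", "b1", "b2", "b3"), k = 1)

  g_off <- build_cohort_graph(pairs, knn, use_weak = FALSE)
  expect_length(g_off$components, 2)
  expect_true(all(g_off$edges$kind == "mnn"))

  g_on <- build_cohort_graph(pairs, knn, use_weak = TRUE)
  expect_length(g_on$components, 1)
  expect_setequal(g_on$components[[1]], c("A", "A2", "B", "C"))
  weak <- g_on$edges[g_on$edges$kind == "weak", ]
  expect_equal(nrow(weak), 1L)
  expect_setequal(c(weak$from, weak$to), c("B", "C"))

  # weak edges are skipped when the MNN partners share a batch
  pairs_same <- pairs
  pairs_same$batch_b <- c("b2", "b2")
  g_same <- build_cohort_graph(pairs_same, knn, use_weak = TRUE)
  expect_false(any(g_same$edges$kind == "weak"))
})

test_that("components match the union-find oracle; weak=TRUE coarsens", {
  set.seed(202)
  for (rep in 1:8) {
    n_per <- sample(8:20, 1)
    nb <- sample(2:4, 1)
    coords <- matrix(rnorm(nb * n_per * 2), ncol = 2)
    ids <- paste0("c", seq_len(nrow(coords)))
    emb <- toy_embedding(coords, ids)
    batches <- rep(paste0("b", 1:nb), each = n_per)
    ps <- multi_round_mnn(emb, batches, k_mnn = 2, n_rounds = 2,
                          sample_cap = n_per)
    if (nrow(ps) == 0) next
    knn <- within_batch_knn(emb, batches, k = 2)
    g <- build_cohort_graph(ps, knn, use_weak = TRUE)

    want <- oracle_components(g$edges$from, g$edges$to)
    # oracle keeps single-batch components too; filter like the package
    b_of <- g$batch_of
    want <- want[vapply(want, function(cs)
      length(unique(unname(b_of[cs]))) >= 2, logical(1))]
    expect_equal(canonical_components(g$components),
                 canonical_components(want))

    # monotonicity: weak partition coarsens the mnn-only partition
    g0 <- build_cohort_graph(ps, knn, use_weak = FALSE)
    for (comp in g0$components) {
      host <- unique(g$membership[comp])
      expect_length(host[!is.na(host)], 1)
    }
  }
})

test_that("cohort sampler draws one cell per batch, uniformly", {
  pairs <- data.frame(cell_a = c("x", "y"), cell_b = c("z", "z"),
                      batch_a = "b1", batch_b = "b2", round = 1L)
  class(pairs) <- c("pair_set", "data.frame")
  g <- build_cohort_graph(pairs)
  sampler <- extract_cohort_sampler(g)
  set.seed(9)
  draws <- sampler(1000)
  expect_true(all(vapply(draws, length, integer(1)) == 2))
  expect_true(all(vapply(draws, function(d) !anyDuplicated(names(d)), logical(1))))
  # z always present; x vs y split ~ 50/50 (chi-squared GOF)
  b1_cells <- vapply(draws, function(d) d[["b1"]], character(1))
  expect_true(all(vapply(draws, function(d) d[["b2"]], character(1)) == "z"))
  tab <- table(factor(b1_cells, levels = c("x", "y")))
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.001)

  # deterministic cohort for a one-cell-per-batch component
  pairs1 <- pairs[1, ]
  class(pairs1) <- c("pair_set", "data.frame")
  g1 <- build_cohort_graph(pairs1)
  s1 <- extract_cohort_sampler(g1)
  expect_identical(s1(3)[[1]], s1(3)[[2]])
})
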