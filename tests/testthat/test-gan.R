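# A linear critic D(x) = w . x + b is the degenerate case of the critic
# network (no hidden layer); handy for closed-form checks.
linear_critic <- function(w, b = 0) list(W = list(matrix(w, nrow = 1)),
                                         b = list(b), alpha = 0.2)

test_that("critic loss closed forms hold", {
  real <- rbind(c(1, 2), c(0, 1))
  fake <- rbind(c(2, 0), c(1, 1))

  # unit-norm linear critic: ||grad D|| = 1 everywhere -> penalty 0
  w <- c(3, 4) / 5
  critic <- linear_critic(w)
  set.seed(1)
  loss <- critic_loss(real, fake, critic, lambda_gp = 10)
  expected_w1 <- mean(fake %*% w) - mean(real %*% w)
  expect_equal(loss, expected_w1, tolerance = 1e-5)

  # D == 0: expectation terms vanish, penalty = (0 - 1)^2 = 1 -> loss = lambda
  zero <- linear_critic(c(0, 0))
  expect_equal(critic_loss(real, fake, zero, lambda_gp = 10), 10)
  expect_equal(critic_loss(real, fake, zero, lambda_gp = 3.5), 3.5)

  # 1-D toy, D(x) = 2x: loss = 2*mean(fake) - 2*mean(real) + lambda*(2-1)^2
  r1 <- matrix(c(1, 3), 2); f1 <- matrix(c(2, 5), 2)
  two <- linear_critic(2)
  expect_equal(critic_loss(r1, f1, two, lambda_gp = 10),
               2 * mean(f1) - 2 * mean(r1) + 10)

  expect_error(critic_loss(real, fake[1, , drop = FALSE], critic), "shape")
})

test_that("generator and reconstruction losses match hand arithmetic", {
  const <- linear_critic(c(0, 0), b = 3.5)
  expect_equal(generator_loss(rbind(c(1, 2), c(9, 9)), const), -3.5)

  # batch with critic scores {1, 3} -> loss -2
  lin <- linear_critic(1)
  expect_equal(generator_loss(matrix(c(1, 3), 2), lin), -2)

  g <- rbind(c(3, 4)); t <- rbind(c(0, 0))
  expect_equal(reconstruction_loss(g, t, 2), 10)       # ||(3,4)|| * 2
  expect_equal(reconstruction_loss(t, t, 2), 0)
  # homogeneity: scaling residuals by c scales the loss by c
  expect_equal(reconstruction_loss(3 * g, 3 * t, 2),
               3 * reconstruction_loss(g, t, 2))
  expect_error(reconstruction_loss(g, t, 5), "n_genes")
})

test_that("critic parameter gradients match central finite differences", {
  set.seed(21)
  spec <- critic_spec(3, hidden_widths = c(4, 3))
  critic <- imgg:::init_critic(spec)
  X <- matrix(rnorm(5 * 3), 5)
  dy <- runif(5)

  cache <- imgg:::critic_forward(critic, X, keep = TRUE)
  got <- imgg:::critic_param_grads(critic, cache, dy)

  f_of <- function(critic) sum(imgg:::critic_forward(critic, X)$y * dy)
  for (l in seq_along(critic$W)) {
    num_w <- matrix(numeric_grad(function(wv) {
      c2 <- critic; c2$W[[l]] <- matrix(wv, nrow(critic$W[[l]])); f_of(c2)
    }, as.vector(critic$W[[l]])), nrow(critic$W[[l]]))
    expect_equal(got$W[[l]], num_w, tolerance = 1e-6)
    num_b <- numeric_grad(function(bv) {
      c2 <- critic; c2$b[[l]] <- bv; f_of(c2)
    }, critic$b[[l]])
    expect_equal(got$b[[l]], num_b, tolerance = 1e-6)
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(22)
  spec <- critic_spec(3, hidden_widths = c(4))
  critic <- imgg:::init_critic(spec)
  Xhat <- matrix(rnorm(6 * 3), 6)
  lambda <- 10

  got <- imgg:::gradient_penalty(critic, Xhat, lambda)
  pen_of <- function(critic)
    imgg:::gradient_penalty(critic, Xhat, lambda, want_grads = FALSE)$value
  for (l in seq_along(critic$W)) {
    num_w <- matrix(numeric_grad(function(wv) {
      c2 <- critic; c2$W[[l]] <- matrix(wv, nrow(critic$W[[l]])); pen_of(c2)
    }, as.vector(critic$W[[l]])), nrow(critic$W[[l]]))
    expect_equal(got$grads$W[[l]], num_w, tolerance = 1e-5)
    # piecewise-linear activations: biases receive zero penalty gradient
    num_b <- numeric_grad(function(bv) {
      c2 <- critic; c2$b[[l]] <- bv; pen_of(c2)
    }, critic$b[[l]])
    expect_equal(got$grads$b[[l]], num_b, tolerance = 1e-5)
  }
})

test_that("generator backprop matches finite differences through BN blocks", {
  set.seed(23)
  spec <- generator_spec(4, hidden_widths = c(5, 5))
  gen <- imgg:::init_generator(spec)
  X <- matrix(abs(rnorm(6 * 4)), 6)
  C <- matrix(rnorm(6 * 4), 6)   # fixed upstream weights: L = sum(Y * C)

  fw <- imgg:::gen_forward(gen, X, train = TRUE, keep = TRUE)
  got <- imgg:::gen_param_grads(gen, fw$cache, C)

  loss_of <- function(gen) sum(imgg:::gen_forward(gen, X, train = TRUE)$y * C)
  # spot-check a sample of parameters from every tensor kind
  for (l in seq_along(gen$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      p <- gen$blocks[[l]][[nm]]
      idx <- sample(length(p), min(6, length(p)))
      num <- vapply(idx, function(i) {
        h <- 1e-5
        gp <- gen; gp$blocks[[l]][[nm]][i] <- gp$blocks[[l]][[nm]][i] + h
        gm <- gen; gm$blocks[[l]][[nm]][i] <- gm$blocks[[l]][[nm]][i] - h
        (loss_of(gp) - loss_of(gm)) / (2 * h)
      }, numeric(1))
      expect_equal(as.vector(got$blocks[[l]][[nm]])[idx], num,
                   tolerance = 1e-4)
    }
  }
  idx <- sample(length(gen$out$W), 6)
  num <- vapply(idx, function(i) {
    h <- 1e-5
    gp <- gen; gp$out$W[i] <- gp$out$W[i] + h
    gm <- gen; gm$out$W[i] <- gm$out$W[i] - h
    (loss_of(gp) - loss_of(gm)) / (2 * h)
  }, numeric(1))
  expect_equal(as.vector(got$out$W)[idx], num, tolerance = 1e-4)
})

test_that("generator output is non-negative and correction validates genes", {
  set.seed(24)
  spec <- generator_spec(5, c(8))
  gen <- imgg:::init_generator(spec)
  X <- matrix(rnorm(10 * 5), 10)
  y <- imgg:::gen_forward(gen, X, train = TRUE)$y
  expect_true(all(y >= 0))

  model <- structure(list(generator = gen, n_genes = 5), class = "imgg_generator")
  x <- toy_expr(matrix(abs(rnorm(20)), 4, 5), c("b1", "b1", "b2", "b2"))
  out <- correct_expression(x, model)
  expect_true(all(out$matrix >= 0))
  expect_identical(out$cell_ids, x$cell_ids)

  # empty selection of cells corrects to an empty matrix without error
  empty <- suppressWarnings(toy_expr(x$matrix[0, , drop = FALSE],
                                     character(0), cells = character(0)))
  expect_equal(nrow(correct_expression(empty, model)$matrix), 0L)

  wrong <- toy_expr(matrix(1, 2, 3), c("b1", "b2"))
  expect_error(correct_expression(wrong, model), "gene set")
})

test_that("training is seed-deterministic, logs every epoch, and decomposes", {
  set.seed(25)
  n <- 40; g <- 8
  src <- matrix(abs(rnorm(n * g)), n)
  pairs <- structure(list(sources = src, targets = src, n_genes = g,
                          pattern = "mean", draw = seq_len(n),
                          cell_id = paste0("c", 1:n)),
                     class = "training_pairs")
  cfg <- train_config(epochs = 3, batch_size = 16, critic_steps = 2, seed = 11)
  m1 <- train_imgg(pairs, generator_spec(g, c(16)), critic_spec(g, c(12)), cfg)
  m2 <- train_imgg(pairs, generator_spec(g, c(16)), critic_spec(g, c(12)), cfg)
  expect_identical(m1$log, m2$log)
  expect_equal(nrow(m1$log), 3L)
  expect_equal(m1$log$gen_total,
               m1$log$gen_adv + cfg$rec_weight * m1$log$gen_rec)
})

test_that("reconstruction-dominated training moves toward the identity map", {
  set.seed(26)
  n <- 80; g <- 12
  src <- matrix(abs(rnorm(n * g, mean = 1)), n)
  pairs <- structure(list(sources = src, targets = src, n_genes = g,
                          pattern = "mean", draw = seq_len(n),
                          cell_id = paste0("c", 1:n)),
                     class = "training_pairs")
  cfg <- train_config(epochs = 60, batch_size = 40, critic_steps = 1,
                      rec_weight = 100, learning_rate = 1e-3, seed = 7)
  model <- train_imgg(pairs, generator_spec(g, c(24)), critic_spec(g, c(12)),
                      cfg)
  # reconstruction loss drops substantially from its first-epoch level
  expect_lt(model$log$gen_rec[cfg$epochs], model$log$gen_rec[1] / 2)
})
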