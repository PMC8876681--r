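#' Generator specification
#'
#' Residual fully connected generator: each hidden block is Linear ->
#' BatchNorm -> Mish, with an additive skip connection across
#' equal-width blocks and a full-width skip from the input to the
#' pre-activation output; a final ReLU keeps the output in the
#' non-negative range of gene expression.
#'
#' @param n_genes input and output width.
#' @param hidden_widths integer vector of hidden-block widths.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_genes, hidden_widths = c(1024, 1024)) {
  stopifnot(n_genes >= 1, all(hidden_widths >= 1))
  structure(list(n_genes = as.integer(n_genes),
                 hidden_widths = as.integer(hidden_widths)),
            class = "generator_spec")
}

#' Critic specification
#'
#' Fully connected critic (discriminator) scoring expression vectors
#' with a single unconstrained real output. Hidden layers use
#' LeakyReLU; there is deliberately no normalization layer, so the
#' gradient penalty is a valid per-sample quantity.
#'
#' @param n_genes input width.
#' @param hidden_widths integer vector of hidden widths.
#' @param alpha LeakyReLU negative slope.
#' @return a `critic_spec` list.
#' @export
critic_spec <- function(n_genes, hidden_widths = c(256, 256), alpha = 0.2) {
  stopifnot(n_genes >= 1, all(hidden_widths >= 1), alpha >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 hidden_widths = as.integer(hidden_widths),
                 alpha = alpha),
            class = "critic_spec")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.0002).
#' @param lambda_gp gradient-penalty coefficient (default 10, the
#'   WGAN-GP reference value).
#' @param rec_weight weight of the reconstruction loss in the generator
#'   objective (default 1).
#' @param epochs number of passes over the training pairs.
#' @param batch_size minibatch size.
#' @param critic_steps critic updates per generator update (default 5).
#' @param beta1,beta2 Adam moment decay rates (GAN convention 0.5/0.9).
#' @param seed RNG seed; fixes initialization, minibatch order and
#'   interpolation draws, so training is bit-reproducible on CPU.
#' @param penalty_at where the gradient penalty is evaluated:
#'   `"interpolates"` (uniform mixtures of real and generated samples,
#'   the WGAN-GP convention) or `"generated"`.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, lambda_gp = 10,
                         rec_weight = 1, epochs = 300, batch_size = 256,
                         critic_steps = 5, beta1 = 0.5, beta2 = 0.9,
                         seed = 1,
                         penalty_at = c("interpolates", "generated")) {
  stopifnot(learning_rate > 0, lambda_gp >= 0, rec_weight >= 0,
            epochs >= 1, batch_size >= 1, critic_steps >= 1)
  structure(list(learning_rate = learning_rate, lambda_gp = lambda_gp,
                 rec_weight = rec_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 critic_steps = as.integer(critic_steps),
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
                 penalty_at = match.arg(penalty_at)),
            class = "train_config")
}

## ---- critic ----------------------------------------------------------

init_critic <- function(spec) {
  widths <- c(spec$n_genes, spec$hidden_widths, 1L)
  L <- length(widths) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- init_weight(widths[l + 1], widths[l])
    b[[l]] <- rep(0, widths[l + 1])
  }
  list(W = W, b = b, alpha = spec$alpha)
}

# Forward pass; returns per-sample scores and (optionally) the cache of
# pre-activations A and activations H needed for backprop.
critic_forward <- function(critic, X, keep = FALSE) {
  L <- length(critic$W)
  H <- vector("list", L); A <- vector("list", L)
  h <- X
  for (l in seq_len(L - 1)) {
    a <- sweep(h %*% t(critic$W[[l]]), 2, critic$b[[l]], "+")
    A[[l]] <- a
    h <- leaky_relu(a, critic$alpha)
    H[[l]] <- h
  }
  y <- as.vector(h %*% t(critic$W[[L]]) + critic$b[[L]])
  if (!keep) return(list(y = y))
  list(y = y, A = A, H = H, X = X)
}

# Parameter gradients of sum_i dy[i] * D(x_i); dy folds in loss weights.
critic_param_grads <- function(critic, cache, dy) {
  L <- length(critic$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- matrix(dy, ncol = 1)                       # d/dA_L
  h_prev <- if (L > 1) cache$H[[L - 1]] else cache$X
  dW[[L]] <- crossprod(delta, h_prev)
  db[[L]] <- colSums(delta)
  R <- delta %*% critic$W[[L]]
  for (l in seq(L - 1, 1)) {
    if (l < 1) break
    delta <- R * leaky_relu_grad(cache$A[[l]], critic$alpha)
    h_prev <- if (l > 1) cache$H[[l - 1]] else cache$X
    dW[[l]] <- crossprod(delta, h_prev)
    db[[l]] <- colSums(delta)
    R <- delta %*% critic$W[[l]]
  }
  list(W = dW, b = db)
}

# Per-sample gradient of D with respect to its input (n x d matrix),
# plus the intermediate V_l matrices needed for double backprop.
critic_input_grad <- function(critic, cache, keep = FALSE) {
  L <- length(critic$W)
  V <- vector("list", L)
  V[[L]] <- matrix(1, nrow(cache$X), 1)
  R <- V[[L]] %*% critic$W[[L]]
  for (l in seq(L - 1, 1)) {
    if (l < 1) break
    V[[l]] <- R * leaky_relu_grad(cache$A[[l]], critic$alpha)
    R <- V[[l]] %*% critic$W[[l]]
  }
  if (!keep) return(R)
  list(G = R, V = V)
}

# Gradient-penalty value and its parameter gradients at points Xhat.
# Double backprop: the penalty p_i = (||g_i|| - 1)^2 depends on the
# weights both through the backward recursion g = W_1' diag(phi') ...
# and through the pre-activations; with piecewise-linear hidden
# activations the second derivative of the activation is 0 almost
# everywhere, so only the explicit weight appearances contribute and
# biases receive no penalty gradient (exactly what reverse-mode
# autodiff yields for this architecture).
gradient_penalty <- function(critic, Xhat, lambda_gp, want_grads = TRUE) {
  n <- nrow(Xhat)
  cache <- critic_forward(critic, Xhat, keep = TRUE)
  ig <- critic_input_grad(critic, cache, keep = TRUE)
  G <- ig$G; V <- ig$V
  norms <- row_norms(G)
  value <- lambda_gp * mean((norms - 1)^2)
  if (!want_grads) return(list(value = value))

  safe <- pmax(norms, 1e-12)
  w <- (lambda_gp / n) * 2 * (norms - 1) / safe      # dp_i/dG_i = w_i * G_i
  Z <- G * w
  L <- length(critic$W)
  dW <- vector("list", L); db <- vector("list", L)
  for (l in seq_len(L)) {
    dW[[l]] <- crossprod(V[[l]], Z)
    db[[l]] <- rep(0, nrow(critic$W[[l]]))
    if (l < L)
      Z <- (Z %*% t(critic$W[[l]])) * leaky_relu_grad(cache$A[[l]], critic$alpha)
  }
  list(value = value, grads = list(W = dW, b = db))
}

#' Critic (discriminator) loss with gradient penalty
#'
#' The WGAN-GP critic objective:
#' `E[D(x_gen)] - E[D(x_real)] + lambda * E[(||grad D(x_hat)||_2 - 1)^2]`,
#' where `x_hat` are per-sample uniform interpolates
#' `eps * x_real + (1 - eps) * x_gen` (or the generated samples
#' themselves when `penalty_at = "generated"`).
#'
#' @param real_targets,generated numeric matrices (rows = samples) of
#'   equal size.
#' @param critic a critic as returned inside a trained model, or
#'   [critic_spec()] plus `init_critic` internally during training.
#' @param lambda_gp penalty coefficient.
#' @param penalty_at `"interpolates"` or `"generated"`.
#' @return scalar loss value.
#' @export
critic_loss <- function(real_targets, generated, critic, lambda_gp = 10,
                        penalty_at = c("interpolates", "generated")) {
  penalty_at <- match.arg(penalty_at)
  if (!all(dim(real_targets) == dim(generated)))
    stop("real and generated batches must have equal shape")
  y_r <- critic_forward(critic, real_targets)$y
  y_f <- critic_forward(critic, generated)$y
  Xhat <- if (penalty_at == "generated") generated else {
    eps <- stats::runif(nrow(real_targets))
    real_targets * eps + generated * (1 - eps)
  }
  gp <- gradient_penalty(critic, Xhat, lambda_gp, want_grads = FALSE)
  mean(y_f) - mean(y_r) + gp$value
}

#' Generator adversarial loss
#'
#' `-E[D(x_gen)]`: the generator is rewarded when the critic scores its
#' output highly.
#'
#' @param generated numeric matrix of generated samples.
#' @param critic the critic network.
#' @return scalar loss value.
#' @export
generator_loss <- function(generated, critic) {
  -mean(critic_forward(critic, generated)$y)
}

#' Reconstruction loss
#'
#' Mean over the batch of the per-sample Euclidean norm of the residual
#' between generated and target vectors, multiplied by the number of
#' genes: `E[||x_gen - x_target||_2] * n_genes`.
#'
#' @param generated,targets numeric matrices of equal shape.
#' @param n_genes number of genes; must equal the vector length.
#' @return scalar loss value.
#' @export
reconstruction_loss <- function(generated, targets, n_genes) {
  if (!all(dim(generated) == dim(targets)))
    stop("generated and target batches must have equal shape")
  if (ncol(generated) != n_genes)
    stop("n_genes does not match vector length")
  mean(row_norms(generated - targets)) * n_genes
}

## ---- generator -------------------------------------------------------

init_generator <- function(spec) {
  widths <- c(spec$n_genes, spec$hidden_widths)
  B <- length(spec$hidden_widths)
  blocks <- vector("list", B)
  for (l in seq_len(B)) {
    blocks[[l]] <- list(
      W = init_weight(widths[l + 1], widths[l]),
      b = rep(0, widths[l + 1]),
      gamma = rep(1, widths[l + 1]),
      beta = rep(0, widths[l + 1]))
  }
  running <- lapply(seq_len(B), function(l)
    list(mean = rep(0, widths[l + 1]), var = rep(1, widths[l + 1])))
  out <- list(W = init_weight(spec$n_genes, widths[B + 1]),
              b = rep(0, spec$n_genes))
  list(spec = spec, blocks = blocks, out = out, running = running,
       bn_eps = 1e-5, bn_momentum = 0.1)
}

# Forward pass. train mode normalizes by batch statistics (optionally
# updating running statistics); eval mode uses the frozen running
# statistics, so correction of a single cell is well defined.
gen_forward <- function(gen, X, train = FALSE, update_running = FALSE,
                        keep = FALSE) {
  B <- length(gen$blocks)
  n <- nrow(X)
  cache <- if (keep) list(X = X, blocks = vector("list", B)) else NULL
  h <- X
  for (l in seq_len(B)) {
    bl <- gen$blocks[[l]]
    a <- sweep(h %*% t(bl$W), 2, bl$b, "+")
    if (train) {
      mu <- colMeans(a)
      va <- colMeans(sweep(a, 2, mu)^2)          # biased batch variance
      if (update_running) {
        mom <- gen$bn_momentum
        gen$running[[l]]$mean <- (1 - mom) * gen$running[[l]]$mean + mom * mu
        gen$running[[l]]$var <- (1 - mom) * gen$running[[l]]$var +
          mom * va * n / max(1, n - 1)           # unbiased for running
      }
    } else {
      mu <- gen$running[[l]]$mean
      va <- gen$running[[l]]$var
    }
    inv_std <- 1 / sqrt(va + gen$bn_eps)
    ahat <- sweep(sweep(a, 2, mu), 2, inv_std, "*")
    bpre <- sweep(sweep(ahat, 2, bl$gamma, "*"), 2, bl$beta, "+")
    m <- mish(bpre)
    res <- ncol(m) == ncol(h)
    h_new <- if (res) m + h else m
    if (keep)
      cache$blocks[[l]] <- list(h_in = h, a = a, ahat = ahat, bpre = bpre,
                                inv_std = inv_std, residual = res)
    h <- h_new
  }
  o <- sweep(h %*% t(gen$out$W), 2, gen$out$b, "+") + X   # input skip
  y <- pmax(o, 0)
  if (!keep) return(list(y = y, gen = gen))
  cache$h_last <- h; cache$o <- o
  list(y = y, gen = gen, cache = cache)
}

# Parameter gradients of a scalar loss with upstream gradient dY (n x g).
gen_param_grads <- function(gen, cache, dY) {
  B <- length(gen$blocks)
  dO <- dY * (cache$o > 0)
  g_out <- list(W = crossprod(dO, cache$h_last), b = colSums(dO))
  dH <- dO %*% gen$out$W
  g_blocks <- vector("list", B)
  for (l in seq(B, 1)) {
    bl <- gen$blocks[[l]]; cb <- cache$blocks[[l]]
    dM <- dH
    dBpre <- dM * mish_grad(cb$bpre)
    dgamma <- colSums(dBpre * cb$ahat)
    dbeta <- colSums(dBpre)
    dAhat <- sweep(dBpre, 2, bl$gamma, "*")
    n <- nrow(dAhat)
    s1 <- colSums(dAhat)
    s2 <- colSums(dAhat * cb$ahat)
    dA <- sweep(dAhat, 2, s1 / n) - sweep(cb$ahat, 2, s2 / n, "*")
    dA <- sweep(dA, 2, cb$inv_std, "*")
    g_blocks[[l]] <- list(W = crossprod(dA, cb$h_in), b = colSums(dA),
                          gamma = dgamma, beta = dbeta)
    dH_prev <- dA %*% bl$W
    if (cb$residual) dH_prev <- dH_prev + dH
    dH <- dH_prev
  }
  list(blocks = g_blocks, out = g_out)
}

gen_params <- function(gen) list(blocks = gen$blocks, out = gen$out)

gen_set_params <- function(gen, params) {
  gen$blocks <- params$blocks; gen$out <- params$out; gen
}

## ---- training --------------------------------------------------------

#' Train the batch-correction generator (WGAN-GP)
#'
#' Alternating optimization: `critic_steps` critic updates minimizing
#' the gradient-penalized Wasserstein objective, then one generator
#' update minimizing the adversarial loss plus `rec_weight` times the
#' reconstruction loss. Both networks use Adam. Training aborts with a
#' diagnostic if any loss becomes non-finite.
#'
#' @param pairs a [build_training_set()] result.
#' @param gen_spec a [generator_spec()]; default sized from `pairs`.
#' @param crit_spec a [critic_spec()]; default sized from `pairs`.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses?
#' @return An `imgg_generator`: the trained generator plus the critic,
#'   the config and a per-epoch training log (`epoch`, `critic_loss`,
#'   `gen_adv`, `gen_rec`, `gen_total`).
#' @export
train_imgg <- function(pairs, gen_spec = NULL, crit_spec = NULL,
                       config = train_config(), verbose = FALSE) {
  if (nrow(pairs$sources) == 0) stop("training set is empty")
  n_genes <- pairs$n_genes
  if (is.null(gen_spec)) gen_spec <- generator_spec(n_genes)
  if (is.null(crit_spec)) crit_spec <- critic_spec(n_genes)
  if (gen_spec$n_genes != n_genes || crit_spec$n_genes != n_genes)
    stop("network widths do not match the training set's gene count")

  set.seed(config$seed)
  gen <- init_generator(gen_spec)
  critic <- init_critic(crit_spec)
  gen_state <- adam_init(gen_params(gen))
  crit_state <- adam_init(list(W = critic$W, b = critic$b))

  n <- nrow(pairs$sources)
  bs <- min(config$batch_size, n)
  steps <- max(1L, ceiling(n / bs))
  log <- data.frame(epoch = seq_len(config$epochs), critic_loss = NA_real_,
                    gen_adv = NA_real_, gen_rec = NA_real_,
                    gen_total = NA_real_)

  for (epoch in seq_len(config$epochs)) {
    c_losses <- numeric(0); a_losses <- numeric(0); r_losses <- numeric(0)
    for (step in seq_len(steps)) {
      ## critic updates
      for (cs in seq_len(config$critic_steps)) {
        idx <- sample.int(n, bs)
        src <- pairs$sources[idx, , drop = FALSE]
        tgt <- pairs$targets[idx, , drop = FALSE]
        fake <- gen_forward(gen, src, train = TRUE)$y
        cache_r <- critic_forward(critic, tgt, keep = TRUE)
        cache_f <- critic_forward(critic, fake, keep = TRUE)
        g_f <- critic_param_grads(critic, cache_f, rep(1 / bs, bs))
        g_r <- critic_param_grads(critic, cache_r, rep(-1 / bs, bs))
        Xhat <- if (config$penalty_at == "generated") fake else {
          eps <- stats::runif(bs)
          tgt * eps + fake * (1 - eps)
        }
        gp <- gradient_penalty(critic, Xhat, config$lambda_gp)
        c_loss <- mean(cache_f$y) - mean(cache_r$y) + gp$value
        grads <- list(
          W = Map(function(a, b, c) a + b + c, g_f$W, g_r$W, gp$grads$W),
          b = Map(function(a, b, c) a + b + c, g_f$b, g_r$b, gp$grads$b))
        upd <- adam_step(list(W = critic$W, b = critic$b), grads, crit_state,
                         lr = config$learning_rate,
                         beta1 = config$beta1, beta2 = config$beta2)
        critic$W <- upd$params$W; critic$b <- upd$params$b
        crit_state <- upd$state
        c_losses <- c(c_losses, c_loss)
      }
      ## generator update
      idx <- sample.int(n, bs)
      src <- pairs$sources[idx, , drop = FALSE]
      tgt <- pairs$targets[idx, , drop = FALSE]
      fw <- gen_forward(gen, src, train = TRUE, update_running = TRUE,
                        keep = TRUE)
      gen <- fw$gen
      fake <- fw$y
      ## adversarial part: d(-mean D(fake))/dfake via critic backprop
      ccache <- critic_forward(critic, fake, keep = TRUE)
      dFake_adv <- critic_input_grad(critic, ccache) * (-1 / bs)
      adv <- -mean(ccache$y)
      ## reconstruction part: d(n_genes * mean ||r_i||)/dfake
      resid <- fake - tgt
      rn <- pmax(row_norms(resid), 1e-12)
      rec <- mean(row_norms(resid)) * n_genes
      dFake_rec <- resid / rn * (n_genes / bs)
      dFake <- dFake_adv + config$rec_weight * dFake_rec
      grads <- gen_param_grads(gen, fw$cache, dFake)
      upd <- adam_step(gen_params(gen), grads, gen_state,
                       lr = config$learning_rate,
                       beta1 = config$beta1, beta2 = config$beta2)
      gen <- gen_set_params(gen, upd$params)
      gen_state <- upd$state
      a_losses <- c(a_losses, adv); r_losses <- c(r_losses, rec)
    }
    log$critic_loss[epoch] <- mean(c_losses)
    log$gen_adv[epoch] <- mean(a_losses)
    log$gen_rec[epoch] <- mean(r_losses)
    log$gen_total[epoch] <- mean(a_losses) + config$rec_weight * mean(r_losses)
    if (!all(is.finite(unlist(log[epoch, -1]))))
      stop("non-finite loss at epoch ", epoch,
           " (critic=", log$critic_loss[epoch],
           ", gen=", log$gen_total[epoch],
           "); try a lower learning rate or smaller lambda_gp")
    if (verbose)
      message(sprintf("epoch %d: critic %.4f, gen adv %.4f, rec %.4f",
                      epoch, log$critic_loss[epoch], log$gen_adv[epoch],
                      log$gen_rec[epoch]))
  }

  structure(list(generator = gen, critic = critic, config = config,
                 n_genes = n_genes, log = log),
            class = "imgg_generator")
}

#' @export
print.imgg_generator <- function(x, ...) {
  cat("imgg_generator: ", x$n_genes, " genes, ",
      length(x$generator$blocks), " residual blocks, trained ",
      nrow(x$log), " epochs\n", sep = "")
  invisible(x)
}

#' Correct expression with a trained generator
#'
#' Passes every cell (whether or not it belonged to a cohort) through
#' the trained generator in evaluation mode: normalization layers use
#' their frozen running statistics, so the output does not depend on
#' which cells are corrected together. The final ReLU guarantees a
#' non-negative output.
#'
#' @param x a [labeled_expression()] restricted to the training gene
#'   set, in the same gene order.
#' @param model a trained `imgg_generator` from [train_imgg()].
#' @return a [labeled_expression()] of corrected values, same shape and
#'   metadata as `x`.
#' @export
correct_expression <- function(x, model) {
  if (ncol(x$matrix) != model$n_genes)
    stop("gene set does not match the training gene set")
  if (nrow(x$matrix) == 0) return(x)
  y <- gen_forward(model$generator, x$matrix, train = FALSE)$y
  labeled_expression(y, x$gene_names, x$cell_ids, x$batch_labels,
                     x$cell_type_labels, hvg_names = x$hvg_names)
}
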