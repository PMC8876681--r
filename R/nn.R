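# Small neural-network toolkit: activations, initialization and Adam.
# Everything is plain R matrix code; rows are samples throughout.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mish activation: x * tanh(softplus(x))
mish <- function(x) x * tanh(softplus(x))

# d/dx mish(x) = tanh(sp) + x * (1 - tanh(sp)^2) * sigmoid(x)
mish_grad <- function(x) {
  t <- tanh(softplus(x))
  t + x * (1 - t^2) * sigmoid(x)
}

leaky_relu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)

leaky_relu_grad <- function(x, alpha = 0.2) ifelse(x > 0, 1, alpha)

# He-style initialization for a (n_out x n_in) weight matrix.
init_weight <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

# Adam with bias correction over an arbitrary nested list of arrays.
adam_init <- function(params) {
  zeros <- function(p) {
    if (is.list(p)) lapply(p, zeros) else p * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-4,
                      beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# Per-row Euclidean norms.
row_norms <- function(m) sqrt(rowSums(m^2))
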