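# Minimal Adam optimizer over a named list of parameter arrays.
# Used by both the gene-filter autoencoder and the variational autoencoder.

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic minibatch index blocks over a shuffled permutation
.batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
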