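# Shared neural-network primitives: He-normal initialization and a
# hand-rolled Adam optimizer operating on flat lists of parameter arrays.
# Both the variational autoencoder and the 1D convolutional classifier are
# trained through these.

# He-normal weight draw: zero-mean normal with variance 2 / fan_in.
he_normal <- function(dims, fan_in) {
  array(rnorm(prod(dims), mean = 0, sd = sqrt(2 / fan_in)), dim = dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step; returns list(params, state). Standard defaults
# (beta1 0.9, beta2 0.999, eps 1e-8) with bias correction.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}
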