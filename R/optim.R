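# Adam on nested parameter lists, via flatten/relist.

flatten_params <- function(par) unlist(par, use.names = FALSE)

unflatten_params <- function(vec, skeleton) utils::relist(vec, skeleton)

adam_init <- function(par) {
  n <- length(flatten_params(par))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(par, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  g <- flatten_params(grads)
  if (any(!is.finite(g))) stop("non-finite gradient; training diverged")
  p <- flatten_params(par)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(par = unflatten_params(p, par), state = state)
}

# Elementwise sum of two same-shaped nested gradient lists.
add_params <- function(a, b) {
  unflatten_params(flatten_params(a) + flatten_params(b), a)
}

scale_params <- function(a, s) {
  unflatten_params(flatten_params(a) * s, a)
}

zero_params_like <- function(par) {
  unflatten_params(numeric(length(flatten_params(par))), par)
}
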