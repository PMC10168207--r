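# Minimal fully-connected network machinery used by the CVAE: layer stacks
# with LeakyReLU activations, manual backpropagation, and Adam. Kept in base R
# on purpose -- at the matrix sizes this package targets (hundreds of subjects,
# tens of features) BLAS-backed matrix products train the model in seconds.

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x > 0, x, slope * x)
}

leaky_relu_grad <- function(pre, slope = 0.2) {
  ifelse(pre > 0, 1, slope)
}

# One linear layer; initialization mirrors the fan-in-based uniform default of
# mainstream deep-learning frameworks: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
# Draws from the current R RNG stream.
nn_layer <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

# A stack of linear layers; act[l] says whether LeakyReLU follows layer l.
nn_stack <- function(sizes, act) {
  L <- length(sizes) - 1L
  stopifnot(length(act) == L)
  layers <- vector("list", L)
  for (l in seq_len(L)) layers[[l]] <- nn_layer(sizes[l], sizes[l + 1L])
  list(layers = layers, act = act)
}

stack_forward <- function(stack, X, slope = 0.2) {
  L <- length(stack$layers)
  inputs <- vector("list", L)
  pres <- vector("list", L)
  h <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- h
    pre <- h %*% stack$layers[[l]]$W +
      matrix(stack$layers[[l]]$b, nrow(h), length(stack$layers[[l]]$b), byrow = TRUE)
    pres[[l]] <- pre
    h <- if (stack$act[l]) leaky_relu(pre, slope) else pre
  }
  list(out = h, inputs = inputs, pres = pres)
}

# Returns gradients w.r.t. every W/b plus the gradient w.r.t. the stack input.
stack_backward <- function(stack, cache, d_out, slope = 0.2) {
  L <- length(stack$layers)
  grads <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    if (stack$act[l]) d <- d * leaky_relu_grad(cache$pres[[l]], slope)
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], d), b = colSums(d))
    d <- d %*% t(stack$layers[[l]]$W)
  }
  list(grads = grads, d_input = d)
}

adam_state_like <- function(stack) {
  lapply(stack$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

adam_step_stack <- function(stack, grads, state, lr, t,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(stack$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    stack$layers[[l]]$W <- stack$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    stack$layers[[l]]$b <- stack$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(stack = stack, state = state)
}
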