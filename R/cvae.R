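#' CVAE configuration
#'
#' Collects the architecture and training hyperparameters of the conditional
#' variational autoencoder. Defaults follow the published training recipe:
#' 5 pretraining epochs at lambda = 0, 30 cyclically annealed epochs in
#' 5-epoch cycles, 5 final epochs at `lambda_final`, Adam with learning rate
#' 0.01, mini-batches of 64 subjects, `lambda_final = 0.1`.
#'
#' @param input_dim number of features p.
#' @param covariate_dim number of encoded biological covariate columns d.
#' @param batch_dim number of batches B.
#' @param latent_dim latent-space size (1 <= latent_dim <= input_dim).
#' @param hidden_dims integer vector of 4 encoder hidden-layer sizes
#'   (mirrored in the decoder).
#' @param lambda_final final KL weight, >= 0.
#' @param pretrain_epochs,cycle_epochs_total,epochs_per_cycle,final_epochs
#'   training-schedule lengths; `cycle_epochs_total` must be divisible by
#'   `epochs_per_cycle`.
#' @param learning_rate Adam learning rate.
#' @param minibatch_size subjects per optimizer step.
#' @param seed integer seed governing initialization, shuffling and
#'   reparameterization noise.
#' @param activation hidden-layer nonlinearity; only "leaky_relu" (slope 0.2)
#'   is implemented.
#' @param loss_reduction "sum" (the printed overall loss, default) or "mean"
#'   over the mini-batch.
#' @return Object of class `cvae_config`.
#' @export
cvae_config <- function(input_dim, covariate_dim, batch_dim, latent_dim,
                        hidden_dims, lambda_final = 0.1, pretrain_epochs = 5L,
                        cycle_epochs_total = 30L, epochs_per_cycle = 5L,
                        final_epochs = 5L, learning_rate = 0.01,
                        minibatch_size = 64L, seed = 1L,
                        activation = "leaky_relu", loss_reduction = "sum") {
  stopifnot(input_dim >= 2, latent_dim >= 1, latent_dim <= input_dim,
            lambda_final >= 0, learning_rate > 0, minibatch_size >= 1,
            pretrain_epochs >= 0, cycle_epochs_total >= 0, final_epochs >= 0)
  if (cycle_epochs_total > 0 && cycle_epochs_total %% epochs_per_cycle != 0)
    stop("cycle_epochs_total must be divisible by epochs_per_cycle")
  if (!identical(activation, "leaky_relu"))
    stop("only the 'leaky_relu' activation is implemented")
  loss_reduction <- match.arg(loss_reduction, c("sum", "mean"))
  structure(list(input_dim = as.integer(input_dim),
                 covariate_dim = as.integer(covariate_dim),
                 batch_dim = as.integer(batch_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_dims = as.integer(hidden_dims),
                 lambda_final = lambda_final,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 cycle_epochs_total = as.integer(cycle_epochs_total),
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 final_epochs = as.integer(final_epochs),
                 learning_rate = learning_rate,
                 minibatch_size = as.integer(minibatch_size),
                 seed = as.integer(seed),
                 activation = activation,
                 loss_reduction = loss_reduction),
            class = "cvae_config")
}

# Nearest power of 2 to x (integer powers >= 1); exact midpoints round up.
nearest_pow2 <- function(x) {
  if (x <= 1) return(1L)
  lo <- 2^floor(log2(x))
  hi <- 2^ceiling(log2(x))
  if (x - lo < hi - x) as.integer(lo) else as.integer(hi)
}

#' Default CVAE architecture for a given problem size
#'
#' The latent dimension is the power of 2 nearest to p/4 (ties round up;
#' p = 62 gives 16). Four hidden layers interpolate linearly between the
#' encoder input width (p + d + B) and the latent width, so each hidden size
#' sits approximately halfway between its neighbors.
#'
#' @param p number of features (>= 2).
#' @param d number of encoded covariate columns.
#' @param B number of batches.
#' @param ... overrides passed on to [cvae_config()].
#' @return A `cvae_config`.
#' @export
default_architecture <- function(p, d, B, ...) {
  if (p < 2) stop("need at least 2 features")
  latent <- max(1L, min(nearest_pow2(p / 4), as.integer(p)))
  width_in <- p + d + B
  hidden <- round(width_in + (latent - width_in) * seq_len(4) / 5)
  args <- list(input_dim = p, covariate_dim = d, batch_dim = B,
               latent_dim = latent, hidden_dims = as.integer(hidden))
  override <- list(...)
  args[names(override)] <- override
  do.call(cvae_config, args)
}

# Fresh (untrained) model; draws initialization from the current RNG stream.
init_cvae <- function(config) {
  enc_in <- config$input_dim + config$covariate_dim + config$batch_dim
  dec_in <- config$latent_dim + config$covariate_dim + config$batch_dim
  h <- config$hidden_dims
  enc_trunk <- nn_stack(c(enc_in, h), rep(TRUE, length(h)))
  enc_mu <- nn_stack(c(h[length(h)], config$latent_dim), FALSE)
  enc_logvar <- nn_stack(c(h[length(h)], config$latent_dim), FALSE)
  decoder <- nn_stack(c(dec_in, rev(h), config$input_dim),
                      c(rep(TRUE, length(h)), FALSE))
  structure(list(enc_trunk = enc_trunk, enc_mu = enc_mu,
                 enc_logvar = enc_logvar, decoder = decoder,
                 config = config, loss_history = NULL),
            class = "trained_cvae")
}

#' @export
print.trained_cvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<trained_cvae> p = %d, d = %d, B = %d, latent = %d, ",
                     "hidden = [%s]%s\n"),
              cfg$input_dim, cfg$covariate_dim, cfg$batch_dim, cfg$latent_dim,
              paste(cfg$hidden_dims, collapse = ", "),
              if (is.null(x$loss_history)) " (untrained)" else ""))
  invisible(x)
}

as_row_matrix <- function(v, n = NULL) {
  if (is.matrix(v)) return(v)
  m <- matrix(v, nrow = 1)
  if (!is.null(n) && n > 1L) m <- m[rep(1L, n), , drop = FALSE]
  m
}

check_width <- function(m, w, what) {
  if (ncol(m) != w) stop(what, " has width ", ncol(m), ", expected ", w)
  m
}

#' Encode observations into their latent Gaussian parameters
#'
#' Deterministic encoder pass: returns the mean and log-variance defining each
#' subject's diagonal-Gaussian latent distribution. Inputs are expected on the
#' normalized scale (see [apply_normalizer()]).
#'
#' @param model a `trained_cvae`.
#' @param y feature vector (length p) or n x p matrix.
#' @param x covariate vector (length d) or n x d matrix.
#' @param b batch one-hot vector (length B) or n x B matrix; soft weights are
#'   allowed.
#' @return `list(mu, logvar)`, each n x latent_dim.
#' @export
encode <- function(model, y, x, b) {
  cfg <- model$config
  y <- check_width(as_row_matrix(y), cfg$input_dim, "y")
  n <- nrow(y)
  x <- check_width(as_row_matrix(x, n), cfg$covariate_dim, "x")
  b <- check_width(as_row_matrix(b, n), cfg$batch_dim, "b")
  trunk <- stack_forward(model$enc_trunk, cbind(y, x, b))
  list(mu = stack_forward(model$enc_mu, trunk$out)$out,
       logvar = stack_forward(model$enc_logvar, trunk$out)$out)
}

#' Decode latent codes into feature-space reconstructions
#'
#' Deterministic decoder pass; feeding the latent mean gives the "noiseless"
#' reconstruction used at harmonization time.
#'
#' @param model a `trained_cvae`.
#' @param z latent vector (length latent_dim) or n x latent_dim matrix.
#' @inheritParams encode
#' @return n x p matrix of reconstructions on the normalized scale.
#' @export
decode <- function(model, z, x, b) {
  cfg <- model$config
  z <- check_width(as_row_matrix(z), cfg$latent_dim, "z")
  n <- nrow(z)
  x <- check_width(as_row_matrix(x, n), cfg$covariate_dim, "x")
  b <- check_width(as_row_matrix(b, n), cfg$batch_dim, "b")
  stack_forward(model$decoder, cbind(z, x, b))$out
}

#' Reparameterized sample from the latent distribution
#'
#' `z = mu + exp(logvar / 2) * u`, `u ~ N(0, I)` drawn from the current R RNG
#' stream (or from `seed` when given, restoring the stream afterwards).
#'
#' @param mu,logvar vectors or matrices of matching shape.
#' @param seed optional integer for a reproducible draw.
#' @return sample(s) with the shape of `mu`.
#' @export
reparameterized_sample <- function(mu, logvar, seed = NULL) {
  stopifnot(length(mu) == length(logvar))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  u <- stats::rnorm(length(mu))
  if (is.matrix(mu)) u <- matrix(u, nrow(mu), ncol(mu))
  mu + exp(logvar / 2) * u
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)`; non-negative,
#' zero exactly at (mu = 0, logvar = 0).
#'
#' @param mu,logvar numeric vectors (one subject) or matrices (one row per
#'   subject).
#' @return scalar for vector input; per-row vector for matrix input.
#' @export
kl_to_standard_normal <- function(mu, logvar) {
  term <- 0.5 * (exp(logvar) + mu^2 - 1 - logvar)
  if (is.matrix(mu)) rowSums(term) else sum(term)
}

#' CVAE loss
#'
#' Reconstruction is the sum of squared errors over features (and over
#' subjects for matrix input); the total is `reconstruction + lambda * kl`.
#'
#' @param y,y_hat observed and reconstructed features (vector or matrix).
#' @param mu,logvar latent Gaussian parameters.
#' @param lambda_ KL weight, >= 0.
#' @return `list(total, reconstruction, kl)` (sums over all subjects passed).
#' @export
cvae_loss <- function(y, y_hat, mu, logvar, lambda_) {
  stopifnot(lambda_ >= 0)
  recon <- sum((y - y_hat)^2)
  kl <- sum(kl_to_standard_normal(mu, logvar))
  list(total = recon + lambda_ * kl, reconstruction = recon, kl = kl)
}

#' Cyclic-annealing KL weight schedule
#'
#' Epochs and steps are 0-based. lambda is 0 throughout the pretraining
#' epochs; within each annealing cycle it rises linearly (per optimizer step)
#' from 0 at the cycle's first step to `lambda_final` at its last step; it is
#' `lambda_final` throughout the final epochs.
#'
#' @param epoch 0-based epoch index.
#' @param step_in_epoch 0-based optimizer-step index within the epoch.
#' @param steps_per_epoch number of optimizer steps per epoch.
#' @param config a `cvae_config`.
#' @return the KL weight lambda at that step.
#' @export
lambda_schedule <- function(epoch, step_in_epoch, steps_per_epoch, config) {
  total <- config$pretrain_epochs + config$cycle_epochs_total + config$final_epochs
  if (epoch < 0 || epoch >= total)
    stop("epoch ", epoch, " outside the training schedule [0, ", total, ")")
  if (epoch < config$pretrain_epochs) return(0)
  if (epoch >= config$pretrain_epochs + config$cycle_epochs_total)
    return(config$lambda_final)
  cycle_pos <- (epoch - config$pretrain_epochs) %% config$epochs_per_cycle
  idx <- cycle_pos * steps_per_epoch + step_in_epoch
  denom <- config$epochs_per_cycle * steps_per_epoch - 1
  if (denom <= 0) return(config$lambda_final)
  config$lambda_final * idx / denom
}

#' Train the conditional variational autoencoder
#'
#' Runs the pretrain / cyclic-annealing / final schedule with Adam and
#' shuffled mini-batches. All randomness (initialization, shuffling,
#' reparameterization noise) flows from `config$seed`, so a fixed seed gives a
#' bit-identical `loss_history`.
#'
#' @param Yn normalized feature matrix (n x p).
#' @param Xn normalized design matrix (n x d).
#' @param batch_onehot n x B one-hot batch indicator.
#' @param config a `cvae_config`.
#' @param verbose print per-epoch losses.
#' @return A `trained_cvae` with a per-epoch `loss_history` data.frame
#'   (columns epoch, reconstruction, kl, lambda; losses are sums over all
#'   subjects at the lambda in force when each mini-batch was seen).
#' @export
train_cvae <- function(Yn, Xn, batch_onehot, config, verbose = FALSE) {
  Yn <- as.matrix(Yn)
  n <- nrow(Yn)
  Xn <- as.matrix(Xn)
  batch_onehot <- as.matrix(batch_onehot)
  stopifnot(ncol(Yn) == config$input_dim, ncol(Xn) == config$covariate_dim,
            ncol(batch_onehot) == config$batch_dim,
            nrow(Xn) == n, nrow(batch_onehot) == n)

  set.seed(config$seed)
  model <- init_cvae(config)
  st <- list(trunk = adam_state_like(model$enc_trunk),
             mu = adam_state_like(model$enc_mu),
             logvar = adam_state_like(model$enc_logvar),
             dec = adam_state_like(model$decoder))
  lr <- config$learning_rate
  mb <- min(config$minibatch_size, n)
  steps_per_epoch <- ceiling(n / mb)
  total_epochs <- config$pretrain_epochs + config$cycle_epochs_total +
    config$final_epochs
  latent <- config$latent_dim
  hist <- matrix(NA_real_, total_epochs, 3,
                 dimnames = list(NULL, c("reconstruction", "kl", "lambda")))
  t_adam <- 0L

  for (epoch in seq_len(total_epochs) - 1L) {
    perm <- sample.int(n)
    ep_recon <- 0
    ep_kl <- 0
    lam <- 0
    for (step in seq_len(steps_per_epoch) - 1L) {
      rows <- perm[(step * mb + 1L):min((step + 1L) * mb, n)]
      m <- length(rows)
      y <- Yn[rows, , drop = FALSE]
      x <- Xn[rows, , drop = FALSE]
      b <- batch_onehot[rows, , drop = FALSE]
      lam <- lambda_schedule(epoch, step, steps_per_epoch, config)

      trunk <- stack_forward(model$enc_trunk, cbind(y, x, b))
      mu_f <- stack_forward(model$enc_mu, trunk$out)
      lv_f <- stack_forward(model$enc_logvar, trunk$out)
      mu <- mu_f$out
      lv <- pmin(lv_f$out, 30)  # guard exp() overflow early in training
      u <- matrix(stats::rnorm(m * latent), m, latent)
      z <- mu + exp(lv / 2) * u
      dec <- stack_forward(model$decoder, cbind(z, x, b))
      y_hat <- dec$out

      recon <- sum((y - y_hat)^2)
      kl <- sum(0.5 * (exp(lv) + mu^2 - 1 - lv))
      if (!is.finite(recon + kl))
        stop("NaN/Inf loss at epoch ", epoch,
             "; consider lowering the learning rate")
      ep_recon <- ep_recon + recon
      ep_kl <- ep_kl + kl

      scale <- if (config$loss_reduction == "mean") 1 / m else 1
      d_yhat <- 2 * (y_hat - y) * scale
      dec_bw <- stack_backward(model$decoder, dec, d_yhat)
      dz <- dec_bw$d_input[, seq_len(latent), drop = FALSE]
      d_mu <- dz + lam * mu * scale
      d_lv <- dz * u * 0.5 * exp(lv / 2) + lam * 0.5 * (exp(lv) - 1) * scale
      mu_bw <- stack_backward(model$enc_mu, mu_f, d_mu)
      lv_bw <- stack_backward(model$enc_logvar, lv_f, d_lv)
      trunk_bw <- stack_backward(model$enc_trunk, trunk,
                                 mu_bw$d_input + lv_bw$d_input)

      t_adam <- t_adam + 1L
      up <- adam_step_stack(model$decoder, dec_bw$grads, st$dec, lr, t_adam)
      model$decoder <- up$stack; st$dec <- up$state
      up <- adam_step_stack(model$enc_mu, mu_bw$grads, st$mu, lr, t_adam)
      model$enc_mu <- up$stack; st$mu <- up$state
      up <- adam_step_stack(model$enc_logvar, lv_bw$grads, st$logvar, lr, t_adam)
      model$enc_logvar <- up$stack; st$logvar <- up$state
      up <- adam_step_stack(model$enc_trunk, trunk_bw$grads, st$trunk, lr, t_adam)
      model$enc_trunk <- up$stack; st$trunk <- up$state
    }
    hist[epoch + 1L, ] <- c(ep_recon, ep_kl, lam)
    if (verbose)
      message(sprintf("epoch %3d  recon %10.2f  kl %10.2f  lambda %.4f",
                      epoch, ep_recon, ep_kl, lam))
  }
  model$loss_history <- data.frame(epoch = seq_len(total_epochs) - 1L, hist)
  model
}
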