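test_that("default architecture follows the latent and hidden-size rules", {
  expect_equal(default_architecture(62, 4, 2)$latent_dim, 16L)  # 62/4 -> 16
  expect_equal(default_architecture(8, 0, 2)$latent_dim, 2L)    # exact power
  expect_equal(default_architecture(12, 0, 2)$latent_dim, 4L)   # tie 3 -> 4
  cfg <- default_architecture(62, 4, 2)
  h <- cfg$hidden_dims
  expect_length(h, 4L)
  expect_true(all(diff(c(62 + 4 + 2, h, 16)) < 0))  # strictly decreasing
  chain <- c(62 + 4 + 2, h, 16)
  mids <- (chain[1:4] + chain[3:6]) / 2
  expect_true(all(abs(chain[2:5] - mids) <= 1))
  expect_error(default_architecture(1, 0, 2), "at least 2")
  expect_error(cvae_config(10, 2, 2, 4, c(8, 7, 6, 5), cycle_epochs_total = 7,
                           epochs_per_cycle = 5), "divisible")
})

test_that("KL closed form matches identities and a quadrature oracle", {
  expect_equal(kl_to_standard_normal(0, 0), 0)
  expect_equal(kl_to_standard_normal(1, 0), 0.5)
  expect_gt(kl_to_standard_normal(0.3, -1), 0)
  # 1-dim quadrature oracle
  mu <- 0.7
  lv <- 0.3
  s <- exp(lv / 2)
  integrand <- function(z) {
    d <- stats::dnorm(z, mu, s)
    ifelse(d > 0, d * (stats::dnorm(z, mu, s, log = TRUE) -
                         stats::dnorm(z, log = TRUE)), 0)
  }
  oracle <- stats::integrate(integrand, mu - 12 * s, mu + 12 * s,
                             rel.tol = 1e-10)$value
  expect_lt(abs(kl_to_standard_normal(mu, lv) - oracle), 1e-6)
  # matrix input: one value per subject
  m <- kl_to_standard_normal(matrix(c(0, 1), 2, 1), matrix(0, 2, 1))
  expect_equal(m, c(0, 0.5))
})

test_that("loss identities hold", {
  l <- cvae_loss(c(1, 2), c(1, 2), c(0), c(0), 0)
  expect_equal(l$total, 0)
  l2 <- cvae_loss(c(1, 2), c(0, 0), 0, 0, 0)
  expect_equal(l2$reconstruction, 5)  # 1 + 4
  l3 <- cvae_loss(c(1, 2), c(0, 0), 0, 0, 1)
  expect_equal(l3$total, l3$reconstruction)  # KL = 0 at (0, 0)
})

test_that("lambda schedule hits its anchors and ramps linearly per step", {
  cfg <- default_architecture(20, 2, 2)  # lambda_final 0.1, 5/30/5 schedule
  spe <- 6L
  expect_equal(lambda_schedule(0, 0, spe, cfg), 0)
  expect_equal(lambda_schedule(4, spe - 1, spe, cfg), 0)  # end of pretrain
  # last step of each 5-epoch cycle reaches lambda_final exactly
  for (cyc_end in c(9, 14, 19, 24, 29, 34))
    expect_equal(lambda_schedule(cyc_end, spe - 1, spe, cfg), 0.1)
  # first step of each cycle restarts at 0
  for (cyc_start in c(5, 10, 15, 20, 25, 30))
    expect_equal(lambda_schedule(cyc_start, 0, spe, cfg), 0)
  expect_equal(lambda_schedule(37, 3, spe, cfg), 0.1)  # final phase
  # linear, equally spaced increments within a cycle
  lams <- unlist(lapply(5:9, function(e)
    sapply(0:(spe - 1), function(s) lambda_schedule(e, s, spe, cfg))))
  expect_equal(diff(lams), rep(0.1 / (5 * spe - 1), 5 * spe - 1))
  expect_true(all(lams >= 0 & lams <= 0.1))
  expect_error(lambda_schedule(40, 0, spe, cfg), "outside")
})

test_that("reparameterized sampling is correct and reproducible", {
  mu <- c(1, -2)
  expect_lt(max(abs(reparameterized_sample(mu, c(-30, -30), seed = 1) - mu)),
            1e-6)
  z1 <- reparameterized_sample(mu, c(0, 0), seed = 42)
  z2 <- reparameterized_sample(mu, c(0, 0), seed = 42)
  expect_identical(z1, z2)
  set.seed(8)
  draws <- matrix(reparameterized_sample(matrix(1, 1e5, 1), matrix(0, 1e5, 1)),
                  ncol = 1)
  expect_lt(abs(mean(draws) - 1), 4 / sqrt(1e5))
})

test_that("encoder and decoder are deterministic with contracted shapes", {
  cfg <- default_architecture(6, 2, 2, seed = 2)
  set.seed(cfg$seed)
  model <- deepcombat:::init_cvae(cfg)
  y <- matrix(rnorm(12), 2, 6)
  y[2, ] <- y[1, ]
  x <- matrix(0.5, 2, 2)
  b <- matrix(c(1, 1, 0, 0), 2, 2)
  enc <- encode(model, y, x, b)
  expect_equal(enc$mu[1, ], enc$mu[2, ])        # identical subjects
  expect_equal(enc$logvar[1, ], enc$logvar[2, ])
  expect_true(all(is.finite(enc$mu)) && all(is.finite(enc$logvar)))
  expect_equal(ncol(enc$mu), cfg$latent_dim)
  d1 <- decode(model, enc$mu, x, b)
  d2 <- decode(model, enc$mu, x, b)
  expect_identical(d1, d2)
  expect_equal(ncol(d1), 6L)
  expect_error(encode(model, y[, 1:3], x, b), "width")
  expect_error(decode(model, enc$mu[, 1, drop = FALSE], x, b), "width")
})

test_that("analytic gradients match central finite differences", {
  cfg <- cvae_config(4, 1, 2, 2, c(4, 3, 3, 2), seed = 5)
  set.seed(5)
  model <- deepcombat:::init_cvae(cfg)
  n <- 5
  y <- matrix(rnorm(n * 4), n, 4)
  x <- matrix(runif(n), n, 1)
  b <- cbind(rep(c(1, 0), length.out = n), rep(c(0, 1), length.out = n))
  u <- matrix(rnorm(n * 2), n, 2)
  lam <- 0.3

  loss_fn <- function(m) {
    trunk <- deepcombat:::stack_forward(m$enc_trunk, cbind(y, x, b))
    mu <- deepcombat:::stack_forward(m$enc_mu, trunk$out)$out
    lv <- deepcombat:::stack_forward(m$enc_logvar, trunk$out)$out
    z <- mu + exp(lv / 2) * u
    y_hat <- deepcombat:::stack_forward(m$decoder, cbind(z, x, b))$out
    sum((y - y_hat)^2) + lam * sum(0.5 * (exp(lv) + mu^2 - 1 - lv))
  }

  trunk <- deepcombat:::stack_forward(model$enc_trunk, cbind(y, x, b))
  mu_f <- deepcombat:::stack_forward(model$enc_mu, trunk$out)
  lv_f <- deepcombat:::stack_forward(model$enc_logvar, trunk$out)
  mu <- mu_f$out
  lv <- lv_f$out
  z <- mu + exp(lv / 2) * u
  dec <- deepcombat:::stack_forward(model$decoder, cbind(z, x, b))
  d_yhat <- 2 * (dec$out - y)
  dec_bw <- deepcombat:::stack_backward(model$decoder, dec, d_yhat)
  dz <- dec_bw$d_input[, 1:2]
  d_mu <- dz + lam * mu
  d_lv <- dz * u * 0.5 * exp(lv / 2) + lam * 0.5 * (exp(lv) - 1)
  mu_bw <- deepcombat:::stack_backward(model$enc_mu, mu_f, d_mu)
  lv_bw <- deepcombat:::stack_backward(model$enc_logvar, lv_f, d_lv)
  trunk_bw <- deepcombat:::stack_backward(model$enc_trunk, trunk,
                                          mu_bw$d_input + lv_bw$d_input)

  eps <- 1e-6
  check <- function(stack_name, grads, layer, idx) {
    m2 <- model
    m2[[stack_name]]$layers[[layer]]$W[idx] <-
      m2[[stack_name]]$layers[[layer]]$W[idx] + eps
    up <- loss_fn(m2)
    m2[[stack_name]]$layers[[layer]]$W[idx] <-
      m2[[stack_name]]$layers[[layer]]$W[idx] - 2 * eps
    num <- (up - loss_fn(m2)) / (2 * eps)
    expect_lt(abs(num - grads[[layer]]$W[idx]),
              1e-4 * max(1, abs(num)))
  }
  check("decoder", dec_bw$grads, 1, 3)
  check("decoder", dec_bw$grads, 5, 2)
  check("enc_mu", mu_bw$grads, 1, 1)
  check("enc_logvar", lv_bw$grads, 1, 2)
  check("enc_trunk", trunk_bw$grads, 1, 4)
  check("enc_trunk", trunk_bw$grads, 4, 1)
})

test_that("training improves reconstruction, is seeded, and collapses at huge lambda", {
  sim <- sim_small(seed = 2, n = c(100L, 80L), p = 20L)
  nrm <- fit_normalizer(sim$features, sim$design)
  nd <- apply_normalizer(nrm, sim$features, sim$design)
  cfg <- default_architecture(20, ncol(nd$Xn), 2, seed = 3)
  m1 <- train_cvae(nd$Yn, nd$Xn, sim$design$batch_onehot, cfg)
  h <- m1$loss_history
  expect_lt(h$reconstruction[5], h$reconstruction[1])  # pretrain trend
  m2 <- train_cvae(nd$Yn, nd$Xn, sim$design$batch_onehot, cfg)
  expect_identical(m1$loss_history, m2$loss_history)   # seeding contract

  cfg_hi <- default_architecture(20, ncol(nd$Xn), 2, seed = 3,
                                 lambda_final = 1e4)
  m3 <- train_cvae(nd$Yn, nd$Xn, sim$design$batch_onehot, cfg_hi)
  enc <- encode(m3, nd$Yn, nd$Xn, sim$design$batch_onehot)
  expect_lt(mean(abs(enc$mu)), 0.1)  # posterior collapse

  # trained encoder means vary across subjects in informative dimensions
  enc1 <- encode(m1, nd$Yn, nd$Xn, sim$design$batch_onehot)
  expect_gt(max(apply(enc1$mu, 2, stats::sd)), 0.1)
})

test_that("training reconstructs the default simulator to < 0.5 MSE per entry", {
  sim <- sim_full(seed = 1)
  nrm <- fit_normalizer(sim$features, sim$design)
  nd <- apply_normalizer(nrm, sim$features, sim$design)
  cfg <- default_architecture(ncol(nd$Yn), ncol(nd$Xn), 2, seed = 1)
  m <- train_cvae(nd$Yn, nd$Xn, sim$design$batch_onehot, cfg)
  enc <- encode(m, nd$Yn, nd$Xn, sim$design$batch_onehot)
  rec <- decode(m, enc$mu, nd$Xn, sim$design$batch_onehot)
  expect_lt(mean((nd$Yn - rec)^2), 0.5)
})
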