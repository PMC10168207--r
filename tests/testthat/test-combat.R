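test_that("covariate-free fit reproduces hand-computed batch and grand means", {
  toy <- toy_dataset()
  Y <- toy$features$values
  m <- fit_combat(Y, NULL, toy$design$batch_labels, eb = FALSE)
  # equal batch sizes: alpha is the grand mean; batch mean = alpha + gamma*sigma
  expect_equal(unname(m$alpha_hat), unname(colMeans(Y)))
  batch_means_A <- colMeans(Y[1:4, ])
  batch_means_B <- colMeans(Y[5:8, ])
  expect_equal(unname(m$gamma_hat[1, ] * m$sigma_pooled),
               unname(batch_means_A - colMeans(Y)))
  expect_equal(unname(m$gamma_hat[2, ] * m$sigma_pooled),
               unname(batch_means_B - colMeans(Y)))
})

test_that("non-EB estimates recover the generative parameters", {
  # independent errors, gamma/delta^2 drawn from their priors
  sim <- simulate_batch_data(simulation_spec(n_per_batch = c(200L, 200L),
                                             p = 30L, factor_share = 0,
                                             latent_rank = 2L, seed = 42))
  m <- fit_combat(sim$features$values, sim$design$design,
                  sim$design$batch_labels, eb = FALSE)
  rep <- recovery_report(sim$truth, m)
  g <- rep[rep$parameter == "gamma" & rep$estimator == "raw", ]
  expect_lt(g$rmse, g$bound_3se)
  # per-feature additive effects within 3 SE of truth
  wts <- m$n_per_batch / sum(m$n_per_batch)
  gh <- sweep(m$gamma_hat, 2, m$sigma_pooled, "*")
  gh_c <- sweep(gh, 2, as.numeric(crossprod(wts, gh)), "-")
  gt_c <- sweep(sim$truth$gamma, 2,
                as.numeric(crossprod(wts, sim$truth$gamma)), "-")
  se <- sqrt(1 / 200 + 1 / 200)
  expect_lt(max(abs(gh_c - gt_c)), 3 * se)
  # multiplicative effects within 10% of the true pooled-ratio scale
  pooled <- sqrt(as.numeric(crossprod(wts, sim$truth$delta^2)))
  dr <- sweep(sim$truth$delta, 2, pooled, "/")
  expect_lt(max(abs(sqrt(m$delta_hat_sq) - dr) / dr), 0.10)
})

test_that("non-EB correction moment-matches, is idempotent, keeps covariates", {
  sim <- simulate_batch_data(simulation_spec(n_per_batch = c(200L, 200L),
                                             p = 30L, seed = 9))
  Y <- sim$features$values
  X <- sim$design$design
  b <- sim$design$batch_labels
  out <- combat(Y, X, b, eb = FALSE)
  m <- out$model
  corr <- out$corrected
  stand_mean <- matrix(m$alpha_hat, nrow(Y), ncol(Y), byrow = TRUE) +
    X %*% m$beta_hat
  resid <- corr - stand_mean
  for (lev in levels(b)) {
    r <- resid[b == lev, ]
    expect_lt(max(abs(colMeans(r))), 1e-8)
    expect_lt(max(abs(apply(r, 2, stats::var) / m$sigma_pooled^2 - 1)), 1e-6)
  }
  # Idempotence of moment matching is exact for covariate-free designs; with
  # covariates, rescaling residuals by batch-specific delta perturbs the
  # within-batch covariate/residual orthogonality, so a second pass moves the
  # data only by a small amount (see the methods vignette).
  Y0 <- Y
  c1 <- combat(Y0, NULL, b, eb = FALSE)$corrected
  c2 <- combat(c1, NULL, b, eb = FALSE)$corrected
  expect_lt(max(abs(c2 - c1)), 1e-6)
  twice <- combat(corr, X, b, eb = FALSE)$corrected
  expect_lt(max(abs(twice - corr)), 0.05)
  # refitted covariate coefficients match beta_hat closely
  refit <- stats::lm.fit(cbind(stats::model.matrix(~ 0 + b), X), corr)
  expect_lt(max(abs(refit$coefficients[-seq_len(nlevels(b)), ] - m$beta_hat)),
            0.05)
})

test_that("degenerate and identity cases behave as documented", {
  set.seed(3)
  Y <- matrix(rnorm(40), 20, 2)
  m1 <- fit_combat(Y, NULL, rep("only", 20))
  expect_true(m1$identity)
  expect_identical(apply_combat(m1, Y, NULL, rep("only", 20)), Y)
  # gamma* = 0, delta* = 1 model is the identity correction
  m <- fit_combat(Y, NULL, rep(c("A", "B"), 10), eb = FALSE)
  m$gamma_star[] <- 0
  m$delta_star[] <- 1
  expect_equal(apply_combat(m, Y, NULL, rep(c("A", "B"), 10)), Y,
               ignore_attr = TRUE)
})

test_that("EB shrinkage respects its brackets and the eb=FALSE contract", {
  sim <- sim_small(seed = 11, n = c(40L, 30L), p = 25L)
  Y <- sim$features$values
  X <- sim$design$design
  b <- sim$design$batch_labels
  m <- fit_combat(Y, X, b, eb = TRUE)
  m0 <- fit_combat(Y, X, b, eb = FALSE)
  expect_equal(m0$gamma_star, m0$gamma_hat)
  expect_equal(m0$delta_star^2, m0$delta_hat_sq)
  expect_true(all(m$delta_star > 0))
  # gamma* is a convex combination of gamma_hat and the prior mean
  for (i in 1:2) {
    pr <- m$prior_hyperparams[[m$batch_levels[i]]]
    lo <- pmin(m$gamma_hat[i, ], pr$gamma_bar) - 1e-10
    hi <- pmax(m$gamma_hat[i, ], pr$gamma_bar) + 1e-10
    expect_true(all(m$gamma_star[i, ] >= lo & m$gamma_star[i, ] <= hi))
    # delta*^2 sits between its data term sum2/n and the prior mean
    ni <- m$n_per_batch[i]
    stand_mean <- matrix(m$alpha_hat, nrow(Y), ncol(Y), byrow = TRUE) +
      X %*% m$beta_hat
    Z <- (Y - stand_mean) / matrix(m$sigma_pooled, nrow(Y), ncol(Y), byrow = TRUE)
    sum2 <- colSums(sweep(Z[b == m$batch_levels[i], ], 2,
                          m$gamma_star[i, ], "-")^2)
    prior_mean <- pr$ig_scale / (pr$ig_shape - 1)
    lo <- pmin(sum2 / ni, prior_mean) * (1 - 1e-6)
    hi <- pmax(sum2 / ni, prior_mean) * (1 + 1e-6)
    d2 <- m$delta_star[i, ]^2
    expect_true(all(d2 >= lo * 0.9 & d2 <= hi * 1.1))
  }
})

test_that("rank-deficient and degenerate designs are rejected with names", {
  set.seed(4)
  Y <- matrix(rnorm(40), 20, 2)
  b <- rep(c("A", "B"), each = 10)
  X <- cbind(dup = as.numeric(b == "A"))  # collinear with batch indicator
  expect_error(fit_combat(Y, X, b), "rank-deficient.*dup")
  Yc <- Y
  Yc[b == "A", 1] <- 5  # constant within batch A
  expect_error(fit_combat(Yc, NULL, b), "identical values")
})

test_that("covbat reduces covariance batch effects and is conservative without them", {
  sim <- simulate_batch_data(simulation_spec(nonlinear_batch = FALSE,
                                             cov_batch_rotation = TRUE,
                                             seed = 3))
  Y <- sim$features$values
  X <- sim$design$design
  b <- sim$design$batch_labels
  cb <- combat(Y, X, b)$corrected
  cv <- covbat(Y, X, b, variance_threshold = 0.9)
  frob <- function(M) {
    covs <- lapply(split(seq_len(nrow(M)), b), function(i) stats::cov(M[i, ]))
    norm(covs[[1]] - covs[[2]], "F")
  }
  expect_lt(frob(cv), frob(cb))

  # no covariance batch effect: covbat stays close to combat
  sim0 <- simulate_batch_data(simulation_spec(seed = 4))
  c0 <- combat(sim0$features$values, sim0$design$design,
               sim0$design$batch_labels)$corrected
  v0 <- covbat(sim0$features$values, sim0$design$design,
               sim0$design$batch_labels, variance_threshold = 0.9)
  expect_lt(max(abs(c0 - v0)), 0.5)  # feature sd is ~1 by construction

  # full-rank threshold keeps dimensions
  v1 <- covbat(sim0$features$values, sim0$design$design,
               sim0$design$batch_labels, variance_threshold = 1.0)
  expect_identical(dim(v1), dim(sim0$features$values))
})
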