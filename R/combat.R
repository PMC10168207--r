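#' Fit the empirical-Bayes ComBat model
#'
#' Per-feature linear model with additive (gamma) and multiplicative (delta)
#' batch effects: `y = alpha + X beta + gamma_i + delta_i * e`,
#' `e ~ N(0, sigma^2)`. Least-squares alpha/beta, internal standardization by
#' the pooled residual sd, and — with `eb = TRUE` — method-of-moments prior
#' hyperparameters (normal prior on gamma, inverse-gamma on delta^2) with
#' iterative conditional posterior means for the shrunken estimates
#' (Johnson et al. 2007 recipe; tolerance 1e-4, max 100 iterations).
#'
#' `delta_star` is on the standard-deviation scale: `delta_star^2` equals the
#' per-batch variance ratio of standardized residuals, and with `eb = FALSE`
#' it equals `delta_hat_sq` exactly.
#'
#' @param Y numeric matrix (n x p).
#' @param X numeric design matrix of biological covariates (n x d) or NULL.
#' @param batch factor of batch labels, or an n x B one-hot matrix.
#' @param eb use empirical-Bayes shrinkage (TRUE) or raw per-batch
#'   moment estimates (FALSE).
#' @return Object of class `combat_model`.
#' @export
fit_combat <- function(Y, X = NULL, batch, eb = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  batch <- as_batch_factor(batch, n)
  B <- nlevels(batch)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  d <- ncol(X)

  if (B == 1L) {
    # No batch contrast exists: the model is the identity by convention.
    return(structure(list(
      alpha_hat = colMeans(Y), beta_hat = matrix(0, d, p),
      gamma_star = matrix(0, 1, p), delta_star = matrix(1, 1, p),
      gamma_hat = matrix(0, 1, p), delta_hat_sq = matrix(1, 1, p),
      sigma_pooled = rep(1, p), prior_hyperparams = list(),
      eb = eb, batch_levels = levels(batch), n_per_batch = n,
      identity = TRUE), class = "combat_model"))
  }

  onehot <- stats::model.matrix(~ 0 + batch)
  colnames(onehot) <- levels(batch)
  W <- cbind(onehot, X)
  if (n <= ncol(W))
    stop("need n > d + B observations to fit ComBat")
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    dropped <- colnames(W)[qrW$pivot[(qrW$rank + 1L):ncol(W)]]
    stop("rank-deficient design (batch collinear with covariates); ",
         "offending column(s): ", paste(dropped, collapse = ", "))
  }
  Bhat <- qr.coef(qrW, Y)              # (B + d) x p
  batch_coef <- Bhat[seq_len(B), , drop = FALSE]
  beta_hat <- if (d > 0L) Bhat[B + seq_len(d), , drop = FALSE] else matrix(0, 0, p)

  ni <- as.numeric(table(batch))
  alpha_hat <- as.numeric(crossprod(ni / n, batch_coef))  # weighted grand mean

  # residual-df denominator: keeps the pooled scale consistent with the
  # (n_i - 1)-denominator batch variances, making covariate-free correction
  # exactly idempotent
  fit_resid <- Y - W %*% Bhat
  sigma_pooled_sq <- colSums(fit_resid^2) / (n - ncol(W))
  if (any(sigma_pooled_sq <= 0))
    stop("feature(s) with zero residual variance: ",
         paste(which(sigma_pooled_sq <= 0), collapse = ", "))
  sigma_pooled <- sqrt(sigma_pooled_sq)

  stand_mean <- matrix(alpha_hat, n, p, byrow = TRUE)
  if (d > 0L) stand_mean <- stand_mean + X %*% beta_hat
  Z <- (Y - stand_mean) / matrix(sigma_pooled, n, p, byrow = TRUE)

  idx <- split(seq_len(n), batch)
  gamma_hat <- t(vapply(idx, function(ii) colMeans(Z[ii, , drop = FALSE]), numeric(p)))
  delta_hat_sq <- t(vapply(idx, function(ii) apply(Z[ii, , drop = FALSE], 2, stats::var),
                           numeric(p)))
  if (any(delta_hat_sq <= 0)) {
    bad <- which(delta_hat_sq <= 0, arr.ind = TRUE)
    stop("batch '", levels(batch)[bad[1, 1]], "' has identical values for feature ",
         bad[1, 2])
  }

  priors <- list()
  if (eb) {
    gamma_star <- matrix(NA_real_, B, p)
    delta_star_sq <- matrix(NA_real_, B, p)
    for (i in seq_len(B)) {
      g_hat <- gamma_hat[i, ]
      d_hat <- delta_hat_sq[i, ]
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      m <- mean(d_hat)
      s2 <- stats::var(d_hat)
      a_prior <- (2 * s2 + m^2) / s2       # inverse-gamma shape
      b_prior <- (m * s2 + m^3) / s2       # inverse-gamma scale
      sol <- eb_iterate(Z[idx[[i]], , drop = FALSE], g_hat, d_hat,
                        g_bar, t2, a_prior, b_prior)
      gamma_star[i, ] <- sol$gamma
      delta_star_sq[i, ] <- sol$delta_sq
      priors[[levels(batch)[i]]] <- list(gamma_bar = g_bar, tau_bar_sq = t2,
                                         ig_shape = a_prior, ig_scale = b_prior)
    }
  } else {
    gamma_star <- gamma_hat
    delta_star_sq <- delta_hat_sq
  }

  structure(list(
    alpha_hat = alpha_hat, beta_hat = beta_hat,
    gamma_star = gamma_star, delta_star = sqrt(delta_star_sq),
    gamma_hat = gamma_hat, delta_hat_sq = delta_hat_sq,
    sigma_pooled = sigma_pooled, prior_hyperparams = priors,
    eb = eb, batch_levels = levels(batch), n_per_batch = ni,
    identity = FALSE), class = "combat_model")
}

# Iterative conditional posterior means for one batch (vectorized over
# features). Zi: ni x p standardized data for this batch.
eb_iterate <- function(Zi, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                       tol = 1e-4, max_iter = 100L) {
  ni <- nrow(Zi)
  g_new <- g_hat
  d_new <- d_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new
    d_old <- d_new
    g_new <- (t2 * ni * g_hat + d_new * g_bar) / (t2 * ni + d_new)
    sum2 <- colSums(sweep(Zi, 2, g_new, "-")^2)
    d_new <- (0.5 * sum2 + b_prior) / (ni / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
    if (change < tol) break
  }
  list(gamma = g_new, delta_sq = d_new)
}

as_batch_factor <- function(batch, n) {
  if (is.matrix(batch)) {
    if (nrow(batch) != n) stop("batch matrix rows != n")
    lev <- colnames(batch)
    if (is.null(lev)) lev <- paste0("batch", seq_len(ncol(batch)))
    batch <- factor(lev[max.col(batch)], levels = lev)
  }
  batch <- droplevels(as.factor(batch))
  if (length(batch) != n) stop("batch length != n")
  batch
}

#' Remove fitted batch effects
#'
#' Applies the ComBat correction
#' `alpha + X beta + (1 / delta_star_i) (y - (alpha + X beta + gamma_star_i))`
#' on the internally standardized scale, mapping every batch to the
#' covariate-adjusted grand mean.
#'
#' @param model a fitted `combat_model`.
#' @inheritParams fit_combat
#' @return corrected numeric matrix (n x p).
#' @export
apply_combat <- function(model, Y, X = NULL, batch) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  if (p != length(model$alpha_hat)) stop("feature count mismatch with model")
  if (isTRUE(model$identity)) return(Y)
  batch <- as_batch_factor(batch, n)
  if (!all(levels(batch) %in% model$batch_levels))
    stop("unknown batch level(s): ",
         paste(setdiff(levels(batch), model$batch_levels), collapse = ", "))
  bi <- match(as.character(batch), model$batch_levels)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$beta_hat)) stop("design column mismatch with model")

  stand_mean <- matrix(model$alpha_hat, n, p, byrow = TRUE)
  if (ncol(X) > 0L) stand_mean <- stand_mean + X %*% model$beta_hat
  sig <- matrix(model$sigma_pooled, n, p, byrow = TRUE)
  Z <- (Y - stand_mean) / sig
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    model$delta_star[bi, , drop = FALSE]
  stand_mean + Zadj * sig
}

#' Fit-and-apply ComBat convenience wrapper
#'
#' @inheritParams fit_combat
#' @return `list(corrected, model)`.
#' @export
combat <- function(Y, X = NULL, batch, eb = TRUE) {
  model <- fit_combat(Y, X, batch, eb = eb)
  list(corrected = apply_combat(model, Y, X, batch), model = model)
}

#' CovBat: ComBat plus principal-component-space ComBat on residuals
#'
#' Step 1 runs standard ComBat. Step 2 projects the corrected residuals onto
#' the principal components explaining at least `variance_threshold` of the
#' residual variance, runs ComBat (no biological covariates) on the retained
#' scores, back-projects, and recombines with the ComBat-corrected means.
#' Corrects covariance-level batch effects that univariate ComBat misses.
#'
#' @inheritParams fit_combat
#' @param variance_threshold fraction of residual variance the retained
#'   principal components must explain, in (0, 1\].
#' @param eb_scores use EB shrinkage in the score-space ComBat; FALSE by
#'   default (scores are few and uncorrelated, shrinkage across them adds
#'   little).
#' @return corrected numeric matrix (n x p).
#' @export
covbat <- function(Y, X = NULL, batch, variance_threshold = 0.9,
                   eb = TRUE, eb_scores = FALSE) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  step1 <- combat(Y, X, batch, eb = eb)
  model <- step1$model
  if (isTRUE(model$identity)) return(step1$corrected)
  stand_mean <- matrix(model$alpha_hat, n, p, byrow = TRUE)
  if (!is.null(X) && ncol(as.matrix(X)) > 0L)
    stand_mean <- stand_mean + as.matrix(X) %*% model$beta_hat
  resid <- step1$corrected - stand_mean

  pc <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  q <- which(varfrac >= variance_threshold - 1e-12)[1L]
  q <- max(q, 2L)  # ComBat needs >= 2 "features"
  scores <- pc$x[, seq_len(q), drop = FALSE]
  adj_scores <- combat(scores, NULL, batch, eb = eb_scores)$corrected
  resid_adj <- resid
  resid_adj <- resid_adj -
    scores %*% t(pc$rotation[, seq_len(q), drop = FALSE]) +
    adj_scores %*% t(pc$rotation[, seq_len(q), drop = FALSE])
  stand_mean + resid_adj
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d feature(s), %d batch(es) [%s], eb = %s\n",
              length(x$alpha_hat), length(x$batch_levels),
              paste(x$batch_levels, collapse = ", "), x$eb))
  invisible(x)
}
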