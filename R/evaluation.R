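# Statistical evaluation battery: k-sample Anderson-Darling tests,
# feature-wise regression, MANOVA with Pillai's trace, kBET, and a minimal
# batch-prediction AUROC.

neglog10 <- function(p) -log10(pmax(p, 1e-300))

# ---------------------------------------------------------------------------
# k-sample Anderson-Darling (Scholz-Stephens A2akN, midrank version)

# A2akN for a list of samples; handles ties via midranks.
ad_statistic <- function(samples) {
  k <- length(samples)
  n_i <- lengths(samples)
  N <- sum(n_i)
  Z <- sort(unlist(samples, use.names = FALSE))
  r <- rle(Z)
  Zstar <- r$values
  lj <- r$lengths
  Bj <- cumsum(lj) - lj / 2
  A <- 0
  for (i in seq_len(k)) {
    s <- sort(samples[[i]])
    cnt_le <- findInterval(Zstar, s)
    cnt_lt <- findInterval(Zstar, s, left.open = TRUE)
    fij <- cnt_le - cnt_lt
    Mij <- cnt_le - fij / 2
    denom <- Bj * (N - Bj) - N * lj / 4
    ok <- denom > 0
    inner <- lj[ok] / N * (N * Mij[ok] - Bj[ok] * n_i[i])^2 / denom[ok]
    A <- A + sum(inner) / n_i[i]
  }
  A * (N - 1) / N
}

# Variance of A2akN under H0 (Scholz-Stephens) and the standardized statistic.
ad_standardize <- function(A2, n_i) {
  k <- length(n_i)
  N <- sum(n_i)
  H <- sum(1 / n_i)
  hs <- cumsum(1 / seq_len(N - 1))
  h <- hs[N - 1]
  i <- seq_len(N - 2)
  g <- sum((h - hs[i]) / (N - i))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma_sq <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  (A2 - (k - 1)) / sqrt(sigma_sq)
}

# Tail p-value from the published interpolation of the standardized
# statistic's null quantiles (valid range [0.001, 0.25]; clamped outside).
ad_p_asymptotic <- function(tm, k) {
  m <- k - 1
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  sig <- c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005, 0.001)
  tj <- b0 + b1 / sqrt(m) + b2 / m
  fit <- stats::lm(log(sig) ~ tj + I(tj^2))
  pred <- sum(stats::coef(fit) * c(1, tm, tm^2))
  min(max(exp(pred), 0.001), 0.25)
}

# Null statistics by Monte Carlo over random label assignments. The statistic
# is distribution-free for continuous data, so one shared null (computed on
# the tie-free ranks 1..N) serves every feature with the same group sizes.
ad_null_stats <- function(n_i, n_null, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- sum(n_i)
  k <- length(n_i)
  labels <- rep(seq_len(k), n_i)
  Bj <- seq_len(N) - 0.5
  denom <- Bj * (N - Bj) - N / 4
  vapply(seq_len(n_null), function(r) {
    lab <- sample(labels)
    A <- 0
    for (i in seq_len(k)) {
      ind <- as.numeric(lab == i)
      Mij <- cumsum(ind) - ind / 2
      A <- A + sum((N * Mij - Bj * n_i[i])^2 / denom / N) / n_i[i]
    }
    A * (N - 1) / N
  }, numeric(1))
}

#' k-sample Anderson-Darling test
#'
#' Midrank version of the Scholz-Stephens k-sample statistic. The default
#' p-value comes from a seeded Monte-Carlo null over random label assignments
#' (distribution-free for continuous data), which is valid over the whole
#' (0, 1) range; `method = "asymptotic"` uses the published interpolation of
#' the standardized statistic's quantiles, which only resolves the rejection
#' tail (p clamped to \[0.001, 0.25\]).
#'
#' @param x numeric vector of pooled observations.
#' @param g group labels (factor-coercible, >= 2 groups).
#' @param method "simulated" or "asymptotic".
#' @param n_null Monte-Carlo null size for `method = "simulated"`.
#' @param seed seed for the Monte-Carlo null.
#' @param null_stats optional precomputed null statistics (from groups of the
#'   same sizes), overriding `n_null`/`seed`.
#' @return `list(statistic, standardized, p_value, method)`.
#' @export
ad_ksample <- function(x, g, method = c("simulated", "asymptotic"),
                       n_null = 2000L, seed = NULL, null_stats = NULL) {
  method <- match.arg(method)
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  samples <- split(as.numeric(x), g)
  A2 <- unname(ad_statistic(samples))
  tm <- unname(ad_standardize(A2, lengths(samples)))
  p <- if (method == "asymptotic") {
    ad_p_asymptotic(tm, length(samples))
  } else {
    if (is.null(null_stats)) null_stats <- ad_null_stats(lengths(samples), n_null, seed)
    (1 + sum(null_stats >= A2 - 1e-12)) / (length(null_stats) + 1)
  }
  list(statistic = A2, standardized = tm, p_value = p, method = method)
}

#' Per-feature Anderson-Darling battery
#'
#' Runs the (two- or k-sample) Anderson-Darling test on every feature, with
#' batch defining the samples, and summarizes the p-values. On
#' well-harmonized data the p-values should look uniform, with mean near 0.5.
#' The Monte-Carlo null is computed once and shared across features (the
#' statistic is distribution-free given the group sizes).
#'
#' @param Y numeric matrix (n x p).
#' @param batch batch labels.
#' @inheritParams ad_ksample
#' @return `list(p_values, mean, sd, statistics, method)`.
#' @export
ad_battery <- function(Y, batch, method = c("simulated", "asymptotic"),
                       n_null = 2000L, seed = 1L) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) != 2L)
    message("ad_battery: ", nlevels(batch),
            " batches; using the k-sample generalization")
  nulls <- if (method == "simulated")
    ad_null_stats(as.integer(table(batch)), n_null, seed) else NULL
  res <- apply(Y, 2, function(col)
    ad_ksample(col, batch, method = method, null_stats = nulls))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  stat <- vapply(res, `[[`, numeric(1), "statistic")
  list(p_values = p, mean = mean(p), sd = stats::sd(p),
       statistics = stat, method = method)
}

# ---------------------------------------------------------------------------

#' Feature-wise regression battery
#'
#' Ordinary least squares per feature with batch plus all biological
#' covariates; reports the two-sided t-test p-value of every non-intercept
#' coefficient as -log10(p), with per-term mean and sd across features, plus
#' Benjamini-Hochberg adjusted columns for convenience.
#'
#' @param Y numeric matrix (n x p).
#' @param X encoded covariate design matrix (n x d), or NULL.
#' @param batch batch labels.
#' @return `list(neglog10_p [p x terms], mean, sd, p_values, p_bh)`.
#' @export
regression_battery <- function(Y, X = NULL, batch) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  batch <- droplevels(as.factor(batch))
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  W <- stats::model.matrix(~batch)
  if (ncol(X) > 0L) W <- cbind(W, X)
  if (qr(W)$rank < ncol(W)) stop("rank-deficient regression design")
  fit <- stats::lm.fit(W, Y)
  rss <- colSums(fit$residuals^2)
  df_res <- n - ncol(W)
  XtXinv <- chol2inv(chol(crossprod(W)))
  se <- sqrt(outer(diag(XtXinv), rss / df_res))      # terms x features
  tval <- t(fit$coefficients) / t(se)                # features x terms
  pv <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  keep <- colnames(W) != "(Intercept)"
  pv <- pv[, keep, drop = FALSE]
  rownames(pv) <- colnames(Y)
  nl <- neglog10(pv)
  p_bh <- apply(pv, 2, stats::p.adjust, method = "BH")
  list(neglog10_p = nl, mean = colMeans(nl), sd = apply(nl, 2, stats::sd),
       p_values = pv, p_bh = p_bh)
}

#' MANOVA with Pillai's trace
#'
#' Multivariate linear model of all features on batch plus covariates;
#' reports the Pillai-trace F-approximation p-value per term as -log10(p).
#' Terms enter sequentially with biological covariates first and batch last,
#' so the batch test is adjusted for the covariates. With a single feature
#' this reduces to the sequential univariate ANOVA F-test.
#'
#' @inheritParams regression_battery
#' @return named numeric vector of -log10 p-values (one per term).
#' @export
manova_pillai <- function(Y, X = NULL, batch) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  batch <- droplevels(as.factor(batch))
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  dat <- data.frame(batch = batch)
  term_names <- character(0)
  if (ncol(X) > 0L) {
    cn <- make.names(colnames(X), unique = TRUE)
    for (j in seq_len(ncol(X))) dat[[cn[j]]] <- X[, j]
    term_names <- cn
  }
  n_terms <- length(term_names) + 1L
  if (n <= p + n_terms)
    stop("MANOVA needs n > p + number of terms; reduce dimension first")
  fml <- stats::as.formula(paste("Y ~", paste(c(term_names, "batch"),
                                              collapse = " + ")))
  if (p == 1L) {
    fit <- stats::lm(fml, data = dat)
    an <- stats::anova(fit)
    pv <- an[["Pr(>F)"]]
    names(pv) <- rownames(an)
    pv <- pv[names(pv) != "Residuals"]
  } else {
    fit <- stats::manova(fml, data = dat)
    ss <- summary(fit, test = "Pillai")$stats
    pv <- ss[, "Pr(>F)"]
    pv <- pv[names(pv) != "Residuals" & !is.na(pv)]
  }
  neglog10(pv)
}

# ---------------------------------------------------------------------------

#' kBET: k-nearest-neighbor batch-effect test
#'
#' Samples a subset of observations, finds each one's k nearest neighbors in
#' Euclidean feature space, and runs a chi-squared goodness-of-fit test of
#' the local batch composition against the global batch proportions. The
#' observed rejection rate is compared against its permutation null (batch
#' labels shuffled, neighborhoods kept) to obtain the overall p-value with
#' the +1 correction.
#'
#' @param Y numeric matrix (n x p), already on the scale to be judged.
#' @param batch batch labels.
#' @param k neighborhood size, or "auto" for `ceiling(0.1 * n)`.
#' @param alpha per-neighborhood rejection level.
#' @param n_permutations label permutations for the null rejection rate.
#' @param subset_fraction fraction of observations tested.
#' @param seed seed for subsampling and permutations.
#' @return Object of class `kbet_result` with `expected_rejection_rate`,
#'   `observed_rejection_rate`, `p_value`, `k`, `n_permutations`,
#'   `subset_fraction`, `seed`.
#' @export
kbet <- function(Y, batch, k = "auto", alpha = 0.05, n_permutations = 100L,
                 subset_fraction = 0.1, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  batch <- droplevels(as.factor(batch))
  B <- nlevels(batch)
  if (identical(k, "auto")) k <- ceiling(0.1 * n)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of observations")
  set.seed(seed)
  n_test <- ceiling(subset_fraction * n)
  test_idx <- sample.int(n, n_test)

  D <- as.matrix(stats::dist(Y))
  neighbors <- matrix(0L, n_test, k)
  for (ii in seq_len(n_test)) {
    i <- test_idx[ii]
    ord <- order(D[i, ])
    neighbors[ii, ] <- setdiff(ord, i)[seq_len(k)]
  }

  global_prop <- as.numeric(table(batch)) / n
  expected <- k * global_prop
  crit <- stats::qchisq(1 - alpha, df = B - 1)
  rejection_rate <- function(labels) {
    rej <- vapply(seq_len(n_test), function(ii) {
      counts <- tabulate(as.integer(labels[neighbors[ii, ]]), nbins = B)
      sum((counts - expected)^2 / expected) > crit
    }, logical(1))
    mean(rej)
  }
  observed <- rejection_rate(batch)
  perm_rates <- vapply(seq_len(n_permutations),
                       function(r) rejection_rate(sample(batch)), numeric(1))
  structure(list(expected_rejection_rate = mean(perm_rates),
                 observed_rejection_rate = observed,
                 p_value = (1 + sum(perm_rates >= observed)) / (n_permutations + 1),
                 k = k, n_permutations = as.integer(n_permutations),
                 subset_fraction = subset_fraction, seed = as.integer(seed)),
            class = "kbet_result")
}

#' @export
print.kbet_result <- function(x, ...) {
  cat(sprintf("<kbet_result> expected %.3f, observed %.3f, p = %.3f (k = %d)\n",
              x$expected_rejection_rate, x$observed_rejection_rate,
              x$p_value, x$k))
  invisible(x)
}

# ---------------------------------------------------------------------------

# Rank-based AUROC of scores for a binary 0/1 truth vector.
auroc_from_scores <- function(scores, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated batch-prediction AUROC
#'
#' Repeated stratified k-fold cross-validation of a ridge-penalized logistic
#' regression predicting batch from the feature matrix — a deliberately
#' minimal probe of multivariate batch predictability. AUROC near 0.5 means
#' the batches are indistinguishable to a linear classifier.
#'
#' @param Y numeric matrix (n x p).
#' @param batch binary batch labels (B = 2).
#' @param n_folds,n_repeats cross-validation layout.
#' @param lambda ridge penalty passed to glmnet.
#' @param seed seed for fold assignment.
#' @return `list(mean, sd, fold_auroc)`.
#' @export
batch_auroc <- function(Y, batch, n_folds = 10L, n_repeats = 5L,
                        lambda = 0.1, seed = 1L) {
  Y <- as.matrix(Y)
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) != 2L) stop("batch_auroc requires exactly 2 batches")
  y01 <- as.integer(batch) - 1L
  tab <- table(batch)
  if (any(tab < n_folds))
    stop("every class needs at least n_folds members")
  set.seed(seed)
  lam_seq <- sort(unique(c(10, 1, lambda)), decreasing = TRUE)
  aucs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    fold <- integer(length(y01))
    for (cl in c(0L, 1L)) {
      idx <- which(y01 == cl)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(Y[tr, , drop = FALSE], y01[tr],
                            family = "binomial", alpha = 0, lambda = lam_seq)
      sc <- as.numeric(stats::predict(fit, Y[!tr, , drop = FALSE], s = lambda))
      aucs <- c(aucs, auroc_from_scores(sc, y01[!tr]))
    }
  }
  aucs <- aucs[!is.na(aucs)]
  list(mean = mean(aucs), sd = stats::sd(aucs), fold_auroc = aucs)
}

#' PCA scatter utility
#'
#' Principal components of the correlation matrix (features scaled to unit
#' variance) with batch labels attached; a quick multivariate look at batch
#' structure. Optionally draws a base-graphics scatter of the first two
#' components.
#'
#' @param Y numeric matrix (n x p).
#' @param batch batch labels.
#' @param n_components components to return.
#' @param plot draw a scatter of PC1 vs PC2.
#' @return data.frame with `batch` and the requested component scores.
#' @export
pca_scatter <- function(Y, batch, n_components = 2L, plot = FALSE) {
  batch <- droplevels(as.factor(batch))
  pc <- stats::prcomp(as.matrix(Y), center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  df <- data.frame(batch = batch, pc$x[, seq_len(k), drop = FALSE])
  if (plot) {
    graphics::plot(df[[2]], df[[3]], col = as.integer(df$batch), pch = 19,
                   xlab = "PC1", ylab = "PC2")
    graphics::legend("topright", legend = levels(batch),
                     col = seq_len(nlevels(batch)), pch = 19)
  }
  df
}
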