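#' Fit the invertible normalization step
#'
#' Biological covariates are min-max scaled to \[0, 1\]; features are
#' standardized to mean 0, variance 1 (sample sd, n - 1 denominator). The
#' fitted shift/scale parameters are stored so the harmonized output can be
#' mapped back to the original feature scale exactly.
#'
#' @param features a [feature_matrix()].
#' @param design a [covariate_design()].
#' @return Object of class `normalization_params` with `covariate_min`,
#'   `covariate_range`, `feature_mean`, `feature_sd`.
#' @export
fit_normalizer <- function(features, design) {
  Y <- features$values
  X <- design$design
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  if (any(sdv <= 0))
    stop("constant feature(s): ",
         paste(features$feature_names[sdv <= 0], collapse = ", "))
  if (ncol(X) > 0L) {
    cmin <- apply(X, 2, min)
    crange <- apply(X, 2, max) - cmin
    if (any(crange == 0)) {
      warning("constant covariate column(s): ",
              paste(colnames(X)[crange == 0], collapse = ", "),
              "; passed through unscaled (range set to 1)")
      crange[crange == 0] <- 1
    }
  } else {
    cmin <- numeric(0)
    crange <- numeric(0)
  }
  structure(list(covariate_min = cmin, covariate_range = crange,
                 feature_mean = mu, feature_sd = sdv),
            class = "normalization_params")
}

#' Apply a fitted normalizer
#'
#' @param params a `normalization_params` from [fit_normalizer()].
#' @param features a [feature_matrix()] with the same features.
#' @param design a [covariate_design()] with the same design columns.
#' @return `list(Yn, Xn)`: standardized features and \[0, 1\]-scaled design.
#' @export
apply_normalizer <- function(params, features, design) {
  Y <- features$values
  X <- design$design
  if (ncol(Y) != length(params$feature_mean))
    stop("feature count mismatch with fitted normalizer")
  if (ncol(X) != length(params$covariate_min))
    stop("design column mismatch with fitted normalizer")
  Yn <- sweep(sweep(Y, 2, params$feature_mean, "-"), 2, params$feature_sd, "/")
  Xn <- if (ncol(X) > 0L) {
    sweep(sweep(X, 2, params$covariate_min, "-"), 2, params$covariate_range, "/")
  } else X
  list(Yn = Yn, Xn = Xn)
}

#' Invert feature standardization
#'
#' Maps a matrix on the standardized scale back to the original feature scale:
#' `feature_mean + normalized * feature_sd`, columnwise. Exact inverse of the
#' forward standardization in [apply_normalizer()].
#'
#' @param params a `normalization_params`.
#' @param normalized numeric matrix with `length(params$feature_mean)` columns.
#' @return matrix on the original feature scale.
#' @export
invert_normalizer <- function(params, normalized) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) != length(params$feature_mean))
    stop("column count mismatch with fitted normalizer")
  sweep(sweep(normalized, 2, params$feature_sd, "*"), 2, params$feature_mean, "+")
}
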