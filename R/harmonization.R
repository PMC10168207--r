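#' Resolve the reference batch for counterfactual decoding
#'
#' All subjects are decoded to one common reference batch. `"auto"` picks the
#' largest batch (ties broken by level order), a named level picks that batch,
#' and `"intermediate"` yields uniform soft weights 1/B per batch, fed to the
#' decoder as a non-one-hot indicator.
#'
#' @param design a [covariate_design()].
#' @param request `"auto"`, `"intermediate"`, or a batch level name.
#' @return numeric weight vector of length B (named by batch level).
#' @export
resolve_reference_batch <- function(design, request = "auto") {
  lev <- levels(design$batch_labels)
  B <- length(lev)
  w <- stats::setNames(numeric(B), lev)
  if (identical(request, "auto")) {
    sizes <- table(design$batch_labels)
    w[which.max(sizes)] <- 1
  } else if (identical(request, "intermediate")) {
    w[] <- 1 / B
  } else if (request %in% lev) {
    w[request] <- 1
  } else {
    stop("unknown reference batch '", request, "'; valid levels: ",
         paste(lev, collapse = ", "), " (or \"auto\"/\"intermediate\")")
  }
  w
}

#' DeepComBat harmonization
#'
#' The full three-step pipeline: (1) normalization; (2) CVAE training on the
#' normalized features conditioned on covariates and batch; (3) harmonization,
#' which partitions batch effects into three individually corrected
#' components — ComBat on the noiseless latent means, counterfactual decoding
#' of the corrected latents to a common reference batch (the decoder keeps the
#' unchanged biological covariates), and ComBat on the reconstruction
#' residuals — recombined as `invert_normalizer(y_tilde + eps_combat)`.
#'
#' @param features a [feature_matrix()].
#' @param design a [covariate_design()] aligned with `features`.
#' @param config a [cvae_config()]; NULL uses [default_architecture()] for the
#'   data's dimensions (with `seed` and `lambda_final` applied).
#' @param reference_batch `"auto"` (largest batch, default), a batch level, or
#'   `"intermediate"`.
#' @param eb_latent,eb_residual use EB shrinkage in the latent-space /
#'   residual-space ComBat calls.
#' @param seed,lambda_final convenience overrides applied when `config` is
#'   NULL.
#' @param verbose print training progress.
#' @return Object of class `deepcombat_result`: `harmonized` (a
#'   `feature_matrix` on the original scale) plus all intermediates
#'   (`latent_mu`, `latent_mu_combat`, `decoder_output`, `residuals`,
#'   `residuals_combat`), the trained model, both ComBat models, the
#'   normalization parameters, and the resolved reference batch.
#' @export
deepcombat <- function(features, design, config = NULL,
                       reference_batch = "auto", eb_latent = TRUE,
                       eb_residual = TRUE, seed = 1L, lambda_final = 0.1,
                       verbose = FALSE) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(design, "covariate_design"))
  if (!identical(features$subject_ids, design$subject_ids))
    stop("features and design are not aligned by subject ID")
  p <- ncol(features$values)
  d <- ncol(design$design)
  B <- ncol(design$batch_onehot)
  if (is.null(config))
    config <- default_architecture(p, d, B, seed = seed,
                                   lambda_final = lambda_final)
  ref <- resolve_reference_batch(design, reference_batch)

  norm <- fit_normalizer(features, design)
  nd <- apply_normalizer(norm, features, design)
  Yn <- nd$Yn
  Xn <- nd$Xn
  onehot <- design$batch_onehot
  batch <- design$batch_labels

  model <- train_cvae(Yn, Xn, onehot, config, verbose = verbose)

  enc <- encode(model, Yn, Xn, onehot)
  mu <- enc$mu

  latent_cb <- combat(mu, Xn, batch, eb = eb_latent)  # identity when B = 1
  mu_cb <- latent_cb$corrected

  ref_mat <- matrix(ref, nrow(Yn), B, byrow = TRUE,
                    dimnames = list(NULL, names(ref)))
  y_tilde <- decode(model, mu_cb, Xn, ref_mat)

  y_hat <- decode(model, mu, Xn, onehot)
  eps <- Yn - y_hat
  resid_cb <- combat(eps, Xn, batch, eb = eb_residual)  # identity when B = 1
  eps_cb <- resid_cb$corrected

  harmonized_vals <- invert_normalizer(norm, y_tilde + eps_cb)
  harmonized <- feature_matrix(harmonized_vals,
                               subject_ids = features$subject_ids,
                               feature_names = features$feature_names)

  structure(list(harmonized = harmonized,
                 latent_mu = mu, latent_mu_combat = mu_cb,
                 decoder_output = y_tilde, residuals = eps,
                 residuals_combat = eps_cb,
                 reference_batch = ref,
                 normalization = norm, model = model,
                 latent_combat_model = latent_cb$model,
                 residual_combat_model = resid_cb$model),
            class = "deepcombat_result")
}

#' @export
print.deepcombat_result <- function(x, ...) {
  cat(sprintf("<deepcombat_result> %d subjects x %d features, latent %d, reference: %s\n",
              nrow(x$harmonized$values), ncol(x$harmonized$values),
              ncol(x$latent_mu),
              paste(sprintf("%s=%.2g", names(x$reference_batch),
                            x$reference_batch), collapse = " ")))
  invisible(x)
}

#' Self-harmonization identity check
#'
#' Runs the harmonization pipeline with both ComBat stages disabled and each
#' subject's own batch as the decoding target. The decoder output cancels
#' against the re-injected residual algebraically, so the result equals the
#' input up to floating-point error — for any model weights, trained or not.
#'
#' @param features a [feature_matrix()].
#' @param design the aligned [covariate_design()].
#' @param model a `trained_cvae` (or freshly initialized model) compatible
#'   with the data's dimensions.
#' @param normalization the `normalization_params` fitted on these data.
#' @return a `feature_matrix` that should equal `features`.
#' @export
self_harmonize <- function(features, design, model, normalization) {
  nd <- apply_normalizer(normalization, features, design)
  enc <- encode(model, nd$Yn, nd$Xn, design$batch_onehot)
  y_hat <- decode(model, enc$mu, nd$Xn, design$batch_onehot)
  eps <- nd$Yn - y_hat
  out <- invert_normalizer(normalization, y_hat + eps)
  feature_matrix(out, subject_ids = features$subject_ids,
                 feature_names = features$feature_names)
}
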