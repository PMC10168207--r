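#' Latent log-variance profile
#'
#' Encodes the training data and summarizes the encoder log-variances per
#' latent dimension (mean and median over subjects) plus the pooled
#' distribution over all subjects and dimensions. Informative dimensions have
#' very negative log-variances (the encoder is confident); uninformative ones
#' sit near 0 (the latent law collapses to the N(0, 1) prior). The shape of
#' this distribution drives the `lambda_final` tuning heuristic.
#'
#' @param model a `trained_cvae`.
#' @param Yn,Xn,batch_onehot normalized data the model was trained on.
#' @return Object of class `latent_profile`: `per_dim` data.frame (dimension,
#'   mean_logvar, median_logvar), `pooled` numeric vector (all subjects x
#'   dims), `logvar` the full n x latent matrix.
#' @export
latent_logvar_profile <- function(model, Yn, Xn, batch_onehot) {
  enc <- encode(model, Yn, Xn, batch_onehot)
  lv <- enc$logvar
  per_dim <- data.frame(dimension = seq_len(ncol(lv)),
                        mean_logvar = colMeans(lv),
                        median_logvar = apply(lv, 2, stats::median))
  structure(list(per_dim = per_dim, pooled = as.numeric(lv), logvar = lv),
            class = "latent_profile")
}

#' @export
print.latent_profile <- function(x, ...) {
  cat(sprintf("<latent_profile> %d dims; pooled mean log-variance %.3f\n",
              nrow(x$per_dim), mean(x$pooled)))
  print(x$per_dim, row.names = FALSE)
  invisible(x)
}

#' lambda_final tuning recommendation from the log-variance profile
#'
#' The desirable profile is bimodal: at least one informative dimension
#' (median log-variance below `informative_cutoff`) and at least one
#' uninformative dimension (median above `uninformative_cutoff`). If every
#' dimension is informative the KL weight is too weak (increase lambda, batch
#' effects may hide in the latent space); if every dimension is uninformative
#' the weight is too strong (decrease lambda, reconstructions degrade and
#' batch effects fall into the residuals).
#'
#' @param profile a `latent_profile`.
#' @param informative_cutoff,uninformative_cutoff natural-log variance
#'   thresholds operationalizing "very negative" and "near 0".
#' @return `list(recommendation, n_informative, n_uninformative, n_dims)`
#'   with recommendation one of "ok", "increase_lambda", "decrease_lambda".
#' @export
tuning_recommendation <- function(profile, informative_cutoff = -2,
                                  uninformative_cutoff = -0.5) {
  med <- profile$per_dim$median_logvar
  n_inf <- sum(med < informative_cutoff)
  n_uninf <- sum(med > uninformative_cutoff)
  rec <- if (n_inf >= 1L && n_uninf >= 1L) {
    "ok"
  } else if (n_uninf == 0L) {
    "increase_lambda"
  } else {
    "decrease_lambda"
  }
  list(recommendation = rec, n_informative = n_inf,
       n_uninformative = n_uninf, n_dims = length(med))
}
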