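# Shared fixture builders; everything is generated in code at test time.

# Default-scale simulation with both multivariate batch-effect knobs on.
sim_full <- function(seed = 1, ...) {
  simulate_batch_data(simulation_spec(nonlinear_batch = TRUE,
                                      cov_batch_rotation = TRUE,
                                      seed = seed, ...))
}

# Small, fast simulation for CVAE-dependent tests.
sim_small <- function(seed = 2, n = c(100L, 80L), p = 20L, ...) {
  simulate_batch_data(simulation_spec(n_per_batch = n, p = p, seed = seed,
                                      latent_rank = min(5L, p - 1L), ...))
}

# Reduced training schedule (pretrain 2 + 2 cycles of 2 + final 2) for tests
# that only need a trained model, not a converged one.
quick_config <- function(p, d, B, ...) {
  default_architecture(p, d, B, pretrain_epochs = 2L, cycle_epochs_total = 4L,
                       epochs_per_cycle = 2L, final_epochs = 2L, ...)
}

# Four-subject-per-batch toy dataset with hand-enterable values.
toy_dataset <- function() {
  vals <- matrix(c(1, 2, 3, 4, 6, 7, 8, 9,
                   10, 12, 14, 16, 20, 22, 24, 26), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
  ids <- paste0("s", 1:8)
  features <- feature_matrix(vals, subject_ids = ids)
  design <- covariate_design(NULL, rep(c("A", "B"), each = 4), subject_ids = ids)
  list(features = features, design = design)
}

# Write a simulation to CSV files; returns the two paths.
write_sim_csvs <- function(sim, dir) {
  fpath <- file.path(dir, "features.csv")
  cpath <- file.path(dir, "covariates.csv")
  write_harmonized(sim$features, fpath)
  cov <- data.frame(id = sim$design$subject_ids,
                    batch = as.character(sim$design$batch_labels),
                    sim$design$raw_covariates, check.names = FALSE)
  utils::write.table(cov, cpath, sep = ",", row.names = FALSE, quote = FALSE)
  list(features = fpath, covariates = cpath)
}
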