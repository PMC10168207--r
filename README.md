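# deepcombat

Batch-effect harmonization for multi-batch, subjects-by-features matrices —
for example regional cortical thickness measured on scanners from different
manufacturers — that removes technical batch variation while preserving
biological covariate effects. The package implements the DeepComBat method
(a conditional variational autoencoder combined with empirical-Bayes ComBat),
plus standalone ComBat/CovBat, the statistical evaluation battery used to
judge harmonization quality, latent-space tuning diagnostics, a synthetic
multi-batch data generator with known ground truth, and a command-line
interface.

## The model

ComBat models each feature `k` of subject `j` in batch `i` as

    y_ijk = alpha_k + x_ij' beta_k + gamma_ik + delta_ik e_ijk,   e ~ N(0, sigma_k^2)

with additive (`gamma`) and multiplicative (`delta`) batch effects shrunk by
empirical-Bayes priors across features, and corrects to

    y_ijk^ComBat = alpha_k + x_ij' beta_k + (y_ijk - alpha_k - x_ij' beta_k - gamma*_ik) / delta*_ik.

DeepComBat extends this beyond univariate shifts and scalings. After
normalization (covariates min-max scaled to [0, 1], features standardized), a
fully connected CVAE — encoder `(y, x, b) -> N(mu, diag(sigma))`, decoder
`(z, x, b) -> y_hat` — is trained with the loss

    L = sum_k (y_k - y_hat_k)^2 + lambda * KL( N(mu, diag(sigma)) || N(0, I) )

under a cyclic annealing schedule (5 pretraining epochs at lambda = 0, 30
epochs of 5-epoch linear ramps to lambda_final = 0.1, 5 final epochs; Adam,
learning rate 0.01, mini-batches of 64). Harmonization then partitions batch
effects into three individually corrected components:

1. **Latent ComBat** — ComBat (batch + biological covariates) on the
   noiseless latent means `mu`;
2. **Counterfactual decoding** — `y_tilde = decoder(do(mu_ComBat), x, do(b_R))`,
   every subject decoded to one common reference batch `b_R`;
3. **Residual ComBat** — ComBat on `eps = y - decoder(mu, x, b)`;

recombined as `Mean(y) + (y_tilde + eps_ComBat) * sd(y)`. Self-harmonization
(both ComBat stages off, each subject decoded to its own batch) returns the
input exactly — the residual re-injection cancels the decoder algebraically.

## Worked example

```r
library(deepcombat)

sim <- simulate_batch_data(simulation_spec(nonlinear_batch = TRUE,
                                           cov_batch_rotation = TRUE, seed = 1))
res <- deepcombat(sim$features, sim$design, seed = 1)

kbet(sim$features$values, sim$design$batch_labels, seed = 11)
#> <kbet_result> expected 0.039, observed 0.394, p = 0.010 (k = 33)
kbet(res$harmonized$values, sim$design$batch_labels, seed = 11)
#> <kbet_result> expected 0.043, observed 0.000, p = 1.000 (k = 33)

batch_auroc(sim$features$values, sim$design$batch_labels, seed = 12)$mean
#> [1] 0.9980451
batch_auroc(res$harmonized$values, sim$design$batch_labels, seed = 12)$mean
#> [1] 0.1740602
```

The simulator injects additive/multiplicative univariate batch effects plus a
batch-specific covariance rotation and a mild nonlinear mean shift. On the
raw data the kBET permutation test rejects at its floor (p = 0.010: local
neighborhoods are batch-segregated) and a ridge classifier identifies batch
almost perfectly (AUROC 0.998). After DeepComBat, kBET no longer rejects
(p = 1.0) and cross-validated batch AUROC collapses (values below 0.5 are the
usual anti-learning artifact of full-sample moment matching; anything near or
below chance means batch is no longer predictable). Plain ComBat on the same
data still fails kBET (p = 0.010) because the rotation is invisible to
univariate correction.

Tuning diagnostics:

```r
nrm <- fit_normalizer(sim$features, sim$design)
nd  <- apply_normalizer(nrm, sim$features, sim$design)
prof <- latent_logvar_profile(res$model, nd$Yn, nd$Xn, sim$design$batch_onehot)
tuning_recommendation(prof)$recommendation
#> [1] "ok"        # bimodal log-variance profile: lambda_final is well chosen
```

## Command line

```sh
inst/cli/deepcombat simulate  --seed 1 --out-dir sim/
inst/cli/deepcombat harmonize --features sim/features.csv --covariates sim/covariates.csv \
    --batch-col batch --covariate-cols age,sex,diagnosis --seed 1 --out H.csv
inst/cli/deepcombat evaluate  --features H.csv --covariates sim/covariates.csv \
    --batch-col batch --covariate-cols age,sex,diagnosis --seed 1 --out report.json
```

Subcommands: `simulate`, `combat`, `covbat`, `harmonize`, `tune`, `evaluate`.
Flags beat a `--config cfg.yaml` file, which beats built-in defaults; each
output file gets a `.config.json` sidecar with the effective configuration.

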