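# xpvae — cross-platform proteomics imputation with a joint variational autoencoder

Affinity proteomics platforms (Olink NPX, SomaScan RFU) measure overlapping
protein panels, but paired measurements of the same protein frequently
disagree: different reagents bind different epitopes, dynamic ranges differ,
and each assay has its own noise. Cohorts measured on different platforms can
therefore not simply be pooled. `xpvae` is for analysts who have *some*
samples measured on both platforms and want to harmonize the rest: it learns
a shared latent representation from the paired samples and imputes either
platform's full probe profile from the other, then quantifies how much
downstream science (correlation structure, phenotype associations,
meta-analysis power) the imputed data preserve.

## The model

Two encoders map standardized profiles $x^A_i$, $x^B_i$ to Gaussian
posteriors $(\mu, \log\sigma^2)$ in a shared latent space (reparameterized as
$z = \mu + \sigma \odot \varepsilon$); two decoders map back to each
platform. Training minimizes

$$\mathcal{L} = \lambda_{rec}\,\mathcal{L}_{rec}
  + \lambda_{KL}\,\mathcal{L}_{KL}
  + \lambda_{align}\,\mathcal{L}_{align}
  + \lambda_{cross}\,\mathcal{L}_{cross}$$

with self- and cross-reconstruction $\ell_2$ losses, KL regularization toward
the unit Gaussian prior, and an RBF-kernel maximum-mean-discrepancy term
aligning the two aggregated posteriors (median-heuristic bandwidth per
minibatch, unbiased U-statistic). Defaults: $\lambda_{rec}=0.90$,
$\lambda_{cross}=1.4$, $\lambda_{KL}=1.4\times 10^{-4}$,
$\lambda_{align}=1.9$; three-layer residual MLPs with a dual-head residual
block; AdamW (lr 4e-4, batch 256), Xavier initialization, early stopping on a
dedicated split. Imputation decodes the posterior mean with the *other*
platform's decoder. The networks, losses, and backpropagation are implemented
in plain R and verified by finite-difference gradient checks in the tests.

The package also ships the comparison imputers (Gaussian-kernel KNN with
5-fold CV; a weighted-nearest-neighbor / supervised-PCA pipeline), a permuted
negative control, an evaluation battery (feature-/sample-wise Pearson r,
sex/age-adjusted phenotype associations at 5% FDR, Stouffer z meta-analysis
workflows for mixed-platform cohorts), gradient-based feature attribution
with precision-recall enrichment against reference protein-association edges,
and a synthetic paired-platform generator with known ground truth. See the
methods vignette (`vignettes/cross-platform-imputation.Rmd`) for the full
account.

## Worked example

```r
library(xpvae)

# 1. simulate a paired two-platform cohort with known ground truth
gen <- generate_preset("small", seed = 1)      # N = 600 samples, 60 probes, 10 factors
cohort <- gen$data

# 2. preprocess: feature-wise Z-score each platform, split 60/10/10/20
params_a <- zscore_fit(cohort$A, cohort = "sim")
params_b <- zscore_fit(cohort$B, cohort = "sim")
data <- paired_platforms(zscore_apply(cohort$A, params_a),
                         zscore_apply(cohort$B, params_b),
                         probe_map = cohort$probe_map)
splits <- make_splits(nrow(data$A), seed = 1)

# 3. train a reduced joint VAE
cfg <- network_config(d_a = 60, d_b = 60, d_z = 16, hidden = 128)
model <- jvae_new(cfg, probes_a = data$probes_a, probes_b = data$probes_b, seed = 1)
fit <- train_jvae(model, data, splits,
                  train_config(learning_rate = 1e-3, batch_size = 64,
                               max_epochs = 60, seed = 1))
print(fit$history)
#> train_history: 60 epoch(s), best epoch 59 (early-stop total 42.75613), stopped by max_epochs

# 4. impute platform B for held-out samples and score it
te <- splits$test
imputed <- impute(fit$model, data$A[te, ], direction = "A2B")
print(correlation_report(imputed, data$B[te, ], method = "jvae"))
#> correlation_report [jvae]: median feature r 0.816 (mean 0.812, 0 undefined);
#>   median sample r 0.822 (mean 0.797, 0 undefined)

# 5. the permuted negative control defines the noise floor
perm <- permuted_control(data, seed = 1)
print(correlation_report(perm$B[te, ], data$B[te, ], method = "permuted"))
#> correlation_report [permuted]: median feature r 0.019 (mean 0.021, 0 undefined);
#>   median sample r 0.014 (mean 0.035, 0 undefined)
```

The feature-wise median r of 0.816 says that for a typical probe, imputed
values track the held-out measurements closely; the permuted control's ~0.02
confirms that the signal comes from the learned pairing, not from marginal
structure. Attribution analysis on a trained model
(`importance_matrix()`, `pair_importance()`, `permutation_test()`) then asks
*which* input proteins drive each imputed protein and whether highly
important pairs are enriched for known associations.

A command-line wrapper covering simulate / train / impute / evaluate /
importance lives at `inst/scripts/xpvae` (invoke the installed copy via
`system.file("scripts", "xpvae", package = "xpvae")`).

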