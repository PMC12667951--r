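# Shared fixtures, built once per test run and cached. The trained models are
# the expensive ones; every test that needs "a trained model" reuses these.

.fx <- new.env(parent = emptyenv())

# standardized small cohort (N=600, d=60, K=10) plus splits and phenotypes
fixture_small <- function() {
  if (is.null(.fx$small)) {
    gen <- generate_preset("small", seed = 42)
    sa <- zscore_apply(gen$data$A, zscore_fit(gen$data$A, cohort = "synth1"))
    sb <- zscore_apply(gen$data$B, zscore_fit(gen$data$B, cohort = "synth1"))
    ph <- generate_phenotypes(gen$truth, n_continuous = 3L, n_binary = 2L, seed = 7)
    .fx$small <- list(
      raw = gen$data, truth = gen$truth,
      data = paired_platforms(sa, sb, probe_map = gen$data$probe_map),
      splits = make_splits(nrow(sa), seed = 42),
      pheno = ph)
  }
  .fx$small
}

# reduced-model training protocol used throughout the desk-scale checks
reduced_train_config <- function(seed = 42L, max_epochs = 60L) {
  train_config(learning_rate = 1e-3, batch_size = 64L, max_epochs = max_epochs,
               seed = seed)
}

fixture_small_model <- function() {
  if (is.null(.fx$small_model)) {
    fx <- fixture_small()
    cfg <- network_config(ncol(fx$data$A), ncol(fx$data$B), d_z = 16L, hidden = 128L)
    model <- jvae_new(cfg, probes_a = fx$data$probes_a, probes_b = fx$data$probes_b,
                      seed = 42)
    .fx$small_model <- train_jvae(model, fx$data, fx$splits, reduced_train_config())
  }
  .fx$small_model
}

# standardized medium cohort (N=3000, d=300, K=30) and its trained model
fixture_medium <- function() {
  if (is.null(.fx$medium)) {
    gen <- generate_preset("medium", seed = 42)
    sa <- zscore_apply(gen$data$A, zscore_fit(gen$data$A, cohort = "synth1"))
    sb <- zscore_apply(gen$data$B, zscore_fit(gen$data$B, cohort = "synth1"))
    ph <- generate_phenotypes(gen$truth, n_continuous = 3L, n_binary = 2L, seed = 7)
    .fx$medium <- list(
      raw = gen$data, truth = gen$truth,
      data = paired_platforms(sa, sb, probe_map = gen$data$probe_map),
      splits = make_splits(nrow(sa), seed = 42),
      pheno = ph)
  }
  .fx$medium
}

fixture_medium_model <- function() {
  if (is.null(.fx$medium_model)) {
    fx <- fixture_medium()
    cfg <- network_config(ncol(fx$data$A), ncol(fx$data$B), d_z = 16L, hidden = 128L)
    model <- jvae_new(cfg, probes_a = fx$data$probes_a, probes_b = fx$data$probes_b,
                      seed = 42)
    .fx$medium_model <- train_jvae(model, fx$data, fx$splits, reduced_train_config())
  }
  .fx$medium_model
}

# capacity-matched reduced model (d_z = 32 >= the medium preset's 30 latent
# factors); used where the analysis needs a converged model rather than the
# deliberately bottlenecked d_z = 16 stress configuration
fixture_medium_model32 <- function() {
  if (is.null(.fx$medium_model32)) {
    fx <- fixture_medium()
    cfg <- network_config(ncol(fx$data$A), ncol(fx$data$B), d_z = 32L, hidden = 128L)
    model <- jvae_new(cfg, probes_a = fx$data$probes_a, probes_b = fx$data$probes_b,
                      seed = 42)
    .fx$medium_model32 <- train_jvae(model, fx$data, fx$splits, reduced_train_config())
  }
  .fx$medium_model32
}

# concordant mapped probe IDs (platform B side) of a fixture
concordant_probes <- function(fx) {
  conc_a <- setdiff(fx$data$probe_map$probe_a, fx$truth$discordant)
  list(a = conc_a,
       b = fx$data$probe_map$probe_b[match(conc_a, fx$data$probe_map$probe_a)])
}

# tiny analytically tractable model: identity activations, no batchnorm, no
# dropout -> the whole imputation map is affine
linear_toy_model <- function(d_a = 5L, d_b = 4L, d_z = 3L, hidden = 6L, seed = 3L) {
  cfg <- network_config(d_a, d_b, d_z = d_z, hidden = hidden, dropout = 0,
                        use_batchnorm = FALSE, activation = "identity")
  jvae_new(cfg, probes_a = sprintf("A%02d", seq_len(d_a)),
           probes_b = sprintf("B%02d", seq_len(d_b)), seed = seed)
}

# closed-form affine map (M, c) of a linear-toy cross-imputation direction,
# recovered by probing the network with basis vectors (independent of the
# backward pass): f(x) = x %*% M + c
linear_toy_affine <- function(model, direction) {
  dir_src <- if (toupper(substr(direction, 1, 1)) == "A") model$config$d_a else model$config$d_b
  f <- function(x) impute(model, x, direction)
  zero <- matrix(0, 1L, dir_src)
  c0 <- f(zero)
  M <- vapply(seq_len(dir_src), function(i) {
    e <- zero; e[1L, i] <- 1
    as.numeric(f(e) - c0)
  }, numeric(ncol(c0)))
  list(M = t(M), c = as.numeric(c0))
}

expect_all_finite <- function(x) testthat::expect_true(all(is.finite(unlist(x))))
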