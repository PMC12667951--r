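#' Network configuration for the joint VAE
#'
#' @param d_a,d_b Input widths of the two platforms.
#' @param d_z Latent width (shared space); default 128.
#' @param hidden Hidden width of the residual MLP blocks; default 512.
#' @param dropout Dropout rate on hidden blocks; default 0.1.
#' @param weight_decay Decoupled L2 coefficient used by AdamW; default 1e-4.
#' @param use_batchnorm Batch-normalize hidden blocks; default TRUE. Inference
#'   uses running statistics so single-sample inputs are well defined.
#' @param activation `"relu"` (default) or `"identity"` (analytic linear-toy
#'   mode used by tests).
#' @return A `network_config` list.
#' @export
network_config <- function(d_a, d_b, d_z = 128L, hidden = 512L, dropout = 0.1,
                           weight_decay = 1e-4, use_batchnorm = TRUE,
                           activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  stopifnot(d_a >= 1, d_b >= 1, d_z >= 1, hidden >= 1,
            dropout >= 0, dropout < 1, weight_decay >= 0)
  structure(list(d_a = as.integer(d_a), d_b = as.integer(d_b),
                 d_z = as.integer(d_z), hidden = as.integer(hidden),
                 dropout = dropout, weight_decay = weight_decay,
                 use_batchnorm = isTRUE(use_batchnorm), activation = activation),
            class = "network_config")
}

#' Loss-component weights of the joint objective
#'
#' Defaults are the tuned values of the published model: self-reconstruction
#' 0.90, cross-reconstruction 1.4, KL 1.4e-4, latent alignment (MMD) 1.9. The
#' KL weight is small because each sample contributes many reconstruction
#' errors but few latent dimensions.
#'
#' @param lambda_rec,lambda_cross,lambda_kl,lambda_align Non-negative reals.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_rec = 0.90, lambda_cross = 1.4,
                         lambda_kl = 1.4e-4, lambda_align = 1.9) {
  w <- list(lambda_rec = lambda_rec, lambda_cross = lambda_cross,
            lambda_kl = lambda_kl, lambda_align = lambda_align)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Kernel configuration for the MMD alignment term
#'
#' @param heuristic `"median"` recomputes the bandwidth per minibatch as the
#'   median pairwise Euclidean distance of the pooled latent points;
#'   `"fixed"` uses `gamma` as given.
#' @param gamma Positive bandwidth, required when `heuristic = "fixed"`.
#' @param pooled With the median heuristic, use all pooled pairs (default,
#'   including cross-platform pairs) or within-set pairs only.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(heuristic = c("median", "fixed"), gamma = NULL,
                          pooled = TRUE) {
  heuristic <- match.arg(heuristic)
  if (heuristic == "fixed") {
    if (is.null(gamma) || gamma <= 0) stop("fixed heuristic requires gamma > 0")
  }
  structure(list(heuristic = heuristic, gamma = gamma, pooled = isTRUE(pooled)),
            class = "kernel_config")
}

#' Build a joint VAE: two encoders and two decoders over a shared latent space
#'
#' @param config A [network_config()].
#' @param weights A [loss_weights()].
#' @param kernel A [kernel_config()].
#' @param seed Integer seed for Xavier initialization (deterministic weights).
#' @param probes_a,probes_b Optional probe universes stored for checkpointing
#'   and external-cohort column matching.
#' @return An object of class `jvae`.
#' @export
jvae_new <- function(config, weights = loss_weights(), kernel = kernel_config(),
                     seed = 1L, probes_a = NULL, probes_b = NULL) {
  stopifnot(inherits(config, "network_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nets <- list(enc_a = dense_net(config$d_a, config$d_z, "encoder", config),
               enc_b = dense_net(config$d_b, config$d_z, "encoder", config),
               dec_a = dense_net(config$d_z, config$d_a, "decoder", config),
               dec_b = dense_net(config$d_z, config$d_b, "decoder", config))
  structure(list(nets = nets, config = config, weights = weights,
                 kernel = kernel, seed = as.integer(seed),
                 probes_a = probes_a, probes_b = probes_b),
            class = "jvae")
}

#' @export
print.jvae <- function(x, ...) {
  cat(sprintf("jvae: d_A=%d, d_B=%d, d_z=%d, hidden=%d, activation=%s, batchnorm=%s\n",
              x$config$d_a, x$config$d_b, x$config$d_z, x$config$hidden,
              x$config$activation, x$config$use_batchnorm))
  invisible(x)
}

.platform_key <- function(platform) {
  platform <- match.arg(toupper(platform), c("A", "B"))
  tolower(platform)
}

#' Encode a batch into its Gaussian posterior in the shared latent space
#'
#' @param model A `jvae`.
#' @param x Batch matrix (samples x platform width).
#' @param platform `"A"` or `"B"`.
#' @param training Use batch statistics / dropout (TRUE during optimization).
#' @return A `latent_posterior`: list with `mu`, `log_var` (batch x d_z) and
#'   the platform tag.
#' @export
encode <- function(model, x, platform, training = FALSE) {
  stopifnot(inherits(model, "jvae"))
  key <- paste0("enc_", .platform_key(platform))
  fw <- .encoder_fwd(model$nets[[key]], x, training = training)
  structure(list(mu = fw$mu, log_var = fw$log_var,
                 platform = toupper(platform)),
            class = "latent_posterior")
}

#' Reparameterization trick: z = mu + exp(log_var / 2) * eps
#'
#' @param posterior A `latent_posterior`.
#' @param epsilon Standard-normal draw of the same shape as `posterior$mu`
#'   (a zero matrix gives the posterior mean).
#' @return Latent batch matrix z.
#' @export
reparameterize <- function(posterior, epsilon) {
  stopifnot(inherits(posterior, "latent_posterior"),
            all(dim(epsilon) == dim(posterior$mu)))
  posterior$mu + exp(0.5 * posterior$log_var) * epsilon
}

#' Decode latent points back to a platform's data space
#'
#' @param model A `jvae`.
#' @param z Latent batch matrix (samples x d_z).
#' @param platform Target platform, `"A"` or `"B"`.
#' @param training Use batch statistics / dropout.
#' @return Reconstruction matrix (samples x platform width).
#' @export
decode <- function(model, z, platform, training = FALSE) {
  stopifnot(inherits(model, "jvae"))
  key <- paste0("dec_", .platform_key(platform))
  .decoder_fwd(model$nets[[key]], z, training = training)$out
}

# ---- loss components -------------------------------------------------------

#' Self-reconstruction loss
#'
#' `(1/2N) * sum_i (||xA_i - xhatA_i||^2 + ||xB_i - xhatB_i||^2)`: the negative
#' log-likelihood under a unit-variance isotropic Gaussian observation model.
#'
#' @param x_a,x_b Input batches.
#' @param xhat_a,xhat_b Reconstructions decoded from each platform's own code.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x_a, x_b, xhat_a, xhat_b) {
  stopifnot(all(dim(x_a) == dim(xhat_a)), all(dim(x_b) == dim(xhat_b)),
            nrow(x_a) == nrow(x_b))
  n <- nrow(x_a)
  (sum((x_a - xhat_a)^2) + sum((x_b - xhat_b)^2)) / (2 * n)
}

#' Cross-reconstruction loss
#'
#' Same functional form as [reconstruction_loss()] with each platform decoded
#' from the other platform's latent code: `xtilde_a = dec_A(z_B)`,
#' `xtilde_b = dec_B(z_A)`. Enforces transferable representations.
#'
#' @param x_a,x_b Input batches.
#' @param xtilde_a,xtilde_b Cross-decoded reconstructions.
#' @return Scalar loss.
#' @export
cross_reconstruction_loss <- function(x_a, x_b, xtilde_a, xtilde_b) {
  reconstruction_loss(x_a, x_b, xtilde_a, xtilde_b)
}

#' KL divergence of both posteriors from the unit Gaussian prior
#'
#' `L_KL = (L^A + L^B)/2` with
#' `L^• = (1/2N) sum_i [ ||mu_i||^2 + exp(log_var_i) - 1 - log_var_i ]`,
#' the bracket summed over latent dimensions.
#'
#' @param posterior_a,posterior_b `latent_posterior` objects.
#' @return Scalar loss (non-negative; zero iff both posteriors equal the prior).
#' @export
kl_loss <- function(posterior_a, posterior_b) {
  0.5 * (.kl_half(posterior_a) + .kl_half(posterior_b))
}

.kl_half <- function(post) {
  n <- nrow(post$mu)
  sum(post$mu^2 + exp(post$log_var) - 1 - post$log_var) / (2 * n)
}

#' RBF kernel between two latent points
#'
#' `k_gamma(u, v) = exp(-||u - v||^2 / (2 gamma^2))`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Positive bandwidth.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(u, v, gamma) {
  stopifnot(length(u) == length(v), gamma > 0)
  exp(-sum((u - v)^2) / (2 * gamma^2))
}

#' Median-heuristic bandwidth for the MMD kernel
#'
#' The median of pairwise Euclidean distances over the pooled latent points
#' (both platforms, cross-platform pairs included by default), floored at a
#' small epsilon so coincident batches do not yield a zero bandwidth.
#'
#' @param z_a,z_b Latent batches (rows are samples).
#' @param pooled Include cross-platform pairs (default) or take the median
#'   over within-platform pairs only.
#' @param floor Lower bound on the bandwidth.
#' @return Positive scalar bandwidth.
#' @export
median_heuristic <- function(z_a, z_b, pooled = TRUE, floor = 1e-8) {
  pts <- rbind(z_a, z_b)
  if (nrow(pts) < 2L) stop("median heuristic needs at least 2 points")
  if (pooled) {
    d <- stats::dist(pts)
  } else {
    d <- c(as.numeric(stats::dist(z_a)), as.numeric(stats::dist(z_b)))
  }
  g <- stats::median(d)
  if (!is.finite(g) || g <= floor) {
    warning("median heuristic degenerate (coincident points); using floor bandwidth")
    g <- floor
  }
  g
}

.sq_dists <- function(x, y) {
  # squared Euclidean distances, rows of x vs rows of y
  xn <- rowSums(x * x); yn <- rowSums(y * y)
  d2 <- outer(xn, yn, "+") - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' MMD alignment loss between the two aggregated posteriors
#'
#' The unbiased U-statistic estimator
#' `(1/(N(N-1))) sum_{i != j} [k(zA_i, zA_j) + k(zB_i, zB_j)]
#'  - (2/N^2) sum_{i,j} k(zA_i, zB_j)`,
#' which may be negative. The bandwidth comes from the model's
#' [kernel_config()] unless `gamma` is supplied.
#'
#' @param z_a,z_b Equal-sized latent batches (N x d_z), N >= 2.
#' @param kernel A [kernel_config()].
#' @param gamma Optional fixed bandwidth overriding `kernel`.
#' @return Scalar loss.
#' @export
mmd_loss <- function(z_a, z_b, kernel = kernel_config(), gamma = NULL) {
  n <- nrow(z_a)
  if (n < 2L) stop("mmd_loss needs batch size >= 2")
  if (nrow(z_b) != n) stop("mmd_loss requires equal batch sizes")
  if (is.null(gamma)) {
    gamma <- if (kernel$heuristic == "fixed") kernel$gamma
             else median_heuristic(z_a, z_b, pooled = kernel$pooled)
  }
  kaa <- exp(-.sq_dists(z_a, z_a) / (2 * gamma^2))
  kbb <- exp(-.sq_dists(z_b, z_b) / (2 * gamma^2))
  kab <- exp(-.sq_dists(z_a, z_b) / (2 * gamma^2))
  (sum(kaa) - n + sum(kbb) - n) / (n * (n - 1)) - 2 * sum(kab) / n^2
}

# gradient of mmd_loss wrt z_a and z_b at fixed gamma (stop-gradient through
# the median heuristic, the standard convention)
.mmd_grad <- function(z_a, z_b, gamma) {
  n <- nrow(z_a)
  kaa <- exp(-.sq_dists(z_a, z_a) / (2 * gamma^2)); diag(kaa) <- 0
  kbb <- exp(-.sq_dists(z_b, z_b) / (2 * gamma^2)); diag(kbb) <- 0
  kab <- exp(-.sq_dists(z_a, z_b) / (2 * gamma^2))
  c1 <- 1 / (n * (n - 1)); c2 <- -2 / n^2
  ig2 <- 1 / gamma^2
  # d/da_i sum_{i!=j} k(a_i,a_j) = -2/g^2 * sum_j K_ij (a_i - a_j)
  da <- -ig2 * (2 * c1 * (z_a * rowSums(kaa) - kaa %*% z_a) +
                  c2 * (z_a * rowSums(kab) - kab %*% z_b))
  db <- -ig2 * (2 * c1 * (z_b * rowSums(kbb) - kbb %*% z_b) +
                  c2 * (z_b * colSums(kab) - t(kab) %*% z_a))
  list(da = da, db = db, gamma = gamma)
}

#' Combine loss components into the weighted total
#'
#' `L_total = lambda_rec L_rec + lambda_KL L_KL + lambda_align L_align +
#' lambda_cross L_cross`; the breakdown is retained for logging.
#'
#' @param rec,cross,kl,align Scalar loss components.
#' @param weights A [loss_weights()].
#' @return A `loss_breakdown` list: `rec`, `cross`, `kl`, `align`, `total`.
#' @export
total_loss <- function(rec, cross, kl, align, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  structure(list(rec = rec, cross = cross, kl = kl, align = align,
                 total = weights$lambda_rec * rec + weights$lambda_cross * cross +
                   weights$lambda_kl * kl + weights$lambda_align * align),
            class = "loss_breakdown")
}

#' Full forward pass of the joint VAE
#'
#' One encode per platform, one reparameterized draw per platform, four
#' decodes (two self, two cross), and the four losses computed on the same
#' draws (one Monte-Carlo sample per item; the same draws feed the
#' cross-reconstruction loss).
#'
#' @param model A `jvae`.
#' @param x_a,x_b Paired standardized batches.
#' @param eps_a,eps_b Optional standard-normal draws (batch x d_z); zero
#'   matrices give the deterministic posterior-mean path; `NULL` draws from
#'   the current RNG.
#' @param training Propagated to encoders/decoders.
#' @return List with `post_a`, `post_b`, `z_a`, `z_b`, `xhat_a`, `xhat_b`,
#'   `xtilde_a`, `xtilde_b`, `loss` (a `loss_breakdown`), `gamma`.
#' @export
jvae_forward <- function(model, x_a, x_b, eps_a = NULL, eps_b = NULL,
                         training = FALSE) {
  stopifnot(inherits(model, "jvae"), nrow(x_a) == nrow(x_b))
  n <- nrow(x_a); dz <- model$config$d_z
  if (is.null(eps_a)) eps_a <- matrix(stats::rnorm(n * dz), n, dz)
  if (is.null(eps_b)) eps_b <- matrix(stats::rnorm(n * dz), n, dz)
  st <- .jvae_forward_caches(model, x_a, x_b, eps_a, eps_b, training)
  st[c("post_a", "post_b", "z_a", "z_b", "xhat_a", "xhat_b",
       "xtilde_a", "xtilde_b", "loss", "gamma")]
}

# forward keeping all layer caches (used by jvae_step and attribution)
.jvae_forward_caches <- function(model, x_a, x_b, eps_a, eps_b, training) {
  ea <- .encoder_fwd(model$nets$enc_a, x_a, training)
  eb <- .encoder_fwd(model$nets$enc_b, x_b, training)
  model$nets$enc_a <- ea$net; model$nets$enc_b <- eb$net
  sig_a <- exp(0.5 * ea$log_var); sig_b <- exp(0.5 * eb$log_var)
  z_a <- ea$mu + sig_a * eps_a
  z_b <- eb$mu + sig_b * eps_b
  da_self <- .decoder_fwd(model$nets$dec_a, z_a, training)
  model$nets$dec_a <- da_self$net
  db_self <- .decoder_fwd(model$nets$dec_b, z_b, training)
  model$nets$dec_b <- db_self$net
  da_cross <- .decoder_fwd(model$nets$dec_a, z_b, training)
  model$nets$dec_a <- da_cross$net
  db_cross <- .decoder_fwd(model$nets$dec_b, z_a, training)
  model$nets$dec_b <- db_cross$net
  post_a <- structure(list(mu = ea$mu, log_var = ea$log_var, platform = "A"),
                      class = "latent_posterior")
  post_b <- structure(list(mu = eb$mu, log_var = eb$log_var, platform = "B"),
                      class = "latent_posterior")
  gamma <- if (model$kernel$heuristic == "fixed") model$kernel$gamma
           else median_heuristic(z_a, z_b, pooled = model$kernel$pooled)
  rec <- reconstruction_loss(x_a, x_b, da_self$out, db_self$out)
  cross <- cross_reconstruction_loss(x_a, x_b, da_cross$out, db_cross$out)
  kl <- kl_loss(post_a, post_b)
  align <- mmd_loss(z_a, z_b, gamma = gamma)
  list(model = model, post_a = post_a, post_b = post_b,
       z_a = z_a, z_b = z_b, sig_a = sig_a, sig_b = sig_b,
       eps_a = eps_a, eps_b = eps_b,
       xhat_a = da_self$out, xhat_b = db_self$out,
       xtilde_a = da_cross$out, xtilde_b = db_cross$out,
       gamma = gamma,
       loss = total_loss(rec, cross, kl, align, model$weights),
       caches = list(ea = ea$cache, eb = eb$cache, da_self = da_self$cache,
                     db_self = db_self$cache, da_cross = da_cross$cache,
                     db_cross = db_cross$cache))
}

# One full forward+backward on a batch: returns loss breakdown, parameter
# gradients for all four nets, and the model (batchnorm running stats updated).
.jvae_step <- function(model, x_a, x_b, eps_a, eps_b, training = TRUE) {
  st <- .jvae_forward_caches(model, x_a, x_b, eps_a, eps_b, training)
  model <- st$model
  w <- model$weights
  n <- nrow(x_a)

  # output-side gradients of the weighted total loss
  d_xhat_a <- w$lambda_rec * (st$xhat_a - x_a) / n
  d_xhat_b <- w$lambda_rec * (st$xhat_b - x_b) / n
  d_xtil_a <- w$lambda_cross * (st$xtilde_a - x_a) / n
  d_xtil_b <- w$lambda_cross * (st$xtilde_b - x_b) / n

  ga_self <- .decoder_bwd(model$nets$dec_a, st$caches$da_self, d_xhat_a)
  gb_self <- .decoder_bwd(model$nets$dec_b, st$caches$db_self, d_xhat_b)
  ga_cross <- .decoder_bwd(model$nets$dec_a, st$caches$da_cross, d_xtil_a)
  gb_cross <- .decoder_bwd(model$nets$dec_b, st$caches$db_cross, d_xtil_b)

  mg <- .mmd_grad(st$z_a, st$z_b, st$gamma)
  dz_a <- ga_self$dx + gb_cross$dx + w$lambda_align * mg$da
  dz_b <- gb_self$dx + ga_cross$dx + w$lambda_align * mg$db

  # KL grads: d/dmu [0.5 * (1/2N) sum(mu^2)] = mu/(2N); d/dlv = (e^lv - 1)/(4N)
  d_mu_a <- dz_a + w$lambda_kl * st$post_a$mu / (2 * n)
  d_mu_b <- dz_b + w$lambda_kl * st$post_b$mu / (2 * n)
  d_lv_a <- dz_a * 0.5 * st$sig_a * st$eps_a +
    w$lambda_kl * (exp(st$post_a$log_var) - 1) / (4 * n)
  d_lv_b <- dz_b * 0.5 * st$sig_b * st$eps_b +
    w$lambda_kl * (exp(st$post_b$log_var) - 1) / (4 * n)

  gea <- .encoder_bwd(model$nets$enc_a, st$caches$ea, d_mu_a, d_lv_a)
  geb <- .encoder_bwd(model$nets$enc_b, st$caches$eb, d_mu_b, d_lv_b)

  grads <- list(enc_a = gea$grads, enc_b = geb$grads,
                dec_a = .add_grads(ga_self$grads, ga_cross$grads),
                dec_b = .add_grads(gb_self$grads, gb_cross$grads))
  list(model = model, loss = st$loss, grads = grads)
}

# deterministic loss evaluation at the posterior mean (eps = 0), eval mode
.jvae_eval_loss <- function(model, x_a, x_b) {
  n <- nrow(x_a); dz <- model$config$d_z
  zero <- matrix(0, n, dz)
  jvae_forward(model, x_a, x_b, eps_a = zero, eps_b = zero,
               training = FALSE)$loss
}
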