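# Minimal dense-network machinery for the joint VAE: linear layers with
# Xavier/Glorot initialization, batch normalization, ReLU, inverted dropout,
# an AdamW optimizer, and explicit backward passes. Gradient correctness is
# enforced by finite-difference checks in the test suite.

.xavier_init <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

.linear_new <- function(fan_in, fan_out) {
  list(W = .xavier_init(fan_in, fan_out), b = numeric(fan_out))
}

.bn_new <- function(width, momentum = 0.1, eps = 1e-5) {
  list(gamma = rep(1, width), beta = numeric(width),
       running_mean = numeric(width), running_var = rep(1, width),
       momentum = momentum, eps = eps)
}

.linear_fwd <- function(layer, x) {
  list(out = sweep(x %*% layer$W, 2L, layer$b, "+"), x = x)
}

# returns input grad and parameter grads
.linear_bwd <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

.bn_fwd <- function(layer, x, training) {
  n <- nrow(x)
  if (training && n > 1L) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    v <- colMeans(xc * xc)                       # biased variance for normalization
    inv_std <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(xc, 2L, inv_std, "*")
    m <- layer$momentum
    layer$running_mean <- (1 - m) * layer$running_mean + m * mu
    layer$running_var <- (1 - m) * layer$running_var + m * v * n / (n - 1)
    out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
    list(out = out, layer = layer,
         cache = list(xhat = xhat, inv_std = inv_std, training = TRUE))
  } else {
    inv_std <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- sweep(sweep(x, 2L, layer$running_mean, "-"), 2L, inv_std, "*")
    out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
    list(out = out, layer = layer,
         cache = list(xhat = xhat, inv_std = inv_std, training = FALSE))
  }
}

.bn_bwd <- function(layer, cache, dout) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, layer$gamma, "*")
  if (cache$training) {
    n <- nrow(dout)
    # full batch-statistics backward
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- sweep(dxhat, 2L, s1 / n, "-") - sweep(cache$xhat, 2L, s2 / n, "*")
    dx <- sweep(dx, 2L, cache$inv_std, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$inv_std, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.act_fwd <- function(x, activation) {
  if (activation == "relu") list(out = pmax(x, 0), mask = x > 0)
  else list(out = x, mask = NULL)                 # identity (linear-toy mode)
}

.act_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

.dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(x), 1L, keep), nrow(x)) / keep
  list(out = x * mask, mask = mask)
}

.dropout_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# One hidden block: linear -> [batchnorm] -> activation -> [dropout].
.block_fwd <- function(net, name, x, training) {
  lin <- .linear_fwd(net$layers[[name]], x)
  h <- lin$out
  bn_cache <- NULL
  if (net$config$use_batchnorm) {
    bn <- .bn_fwd(net$layers[[paste0(name, "_bn")]], h, training)
    net$layers[[paste0(name, "_bn")]] <- bn$layer
    h <- bn$out
    bn_cache <- bn$cache
  }
  act <- .act_fwd(h, net$config$activation)
  drop <- .dropout_fwd(act$out, net$config$dropout, training)
  list(out = drop$out, net = net,
       cache = list(lin = lin, bn = bn_cache, act = act, drop = drop))
}

.block_bwd <- function(net, name, cache, dout, grads) {
  d <- .dropout_bwd(cache$drop, dout)
  d <- .act_bwd(cache$act, d)
  if (net$config$use_batchnorm) {
    bnn <- paste0(name, "_bn")
    bb <- .bn_bwd(net$layers[[bnn]], cache$bn, d)
    grads[[bnn]]$gamma <- grads[[bnn]]$gamma + bb$dgamma
    grads[[bnn]]$beta <- grads[[bnn]]$beta + bb$dbeta
    d <- bb$dx
  }
  lb <- .linear_bwd(net$layers[[name]], cache$lin, d)
  grads[[name]]$W <- grads[[name]]$W + lb$dW
  grads[[name]]$b <- grads[[name]]$b + lb$db
  list(dx = lb$dx, grads = grads)
}

#' Build one encoder or decoder network
#'
#' A three-layer residual MLP: an input linear layer to the hidden width, a
#' dual-head residual block (two parallel hidden blocks whose outputs are
#' summed into the skip connection), and a linear output layer — two heads
#' (posterior mean and log-variance) for an encoder, one reconstruction head
#' for a decoder. Each hidden block is linear -> batchnorm -> activation ->
#' dropout. Weights are Xavier-initialized from the current RNG state.
#'
#' @param d_in,d_out Input width and output width (latent width for encoders).
#' @param kind `"encoder"` or `"decoder"`.
#' @param config Network configuration list (see [network_config()]).
#' @return A `dense_net` list: `layers`, `kind`, `config`.
#' @keywords internal
dense_net <- function(d_in, d_out, kind = c("encoder", "decoder"), config) {
  kind <- match.arg(kind)
  h <- config$hidden
  layers <- list(lin1 = .linear_new(d_in, h),
                 res_a = .linear_new(h, h),
                 res_b = .linear_new(h, h))
  if (config$use_batchnorm) {
    layers$lin1_bn <- .bn_new(h)
    layers$res_a_bn <- .bn_new(h)
    layers$res_b_bn <- .bn_new(h)
  }
  if (kind == "encoder") {
    layers$head_mu <- .linear_new(h, d_out)
    layers$head_lv <- .linear_new(h, d_out)
  } else {
    layers$head_out <- .linear_new(h, d_out)
  }
  list(layers = layers, kind = kind, config = config, d_in = d_in, d_out = d_out)
}

# Forward through the shared body; returns h1 and caches (net returned because
# batchnorm running statistics update in training mode).
.body_fwd <- function(net, x, training) {
  b1 <- .block_fwd(net, "lin1", x, training); net <- b1$net
  ba <- .block_fwd(net, "res_a", b1$out, training); net <- ba$net
  bb <- .block_fwd(net, "res_b", b1$out, training); net <- bb$net
  h1 <- b1$out + ba$out + bb$out                  # dual-head residual block
  list(h1 = h1, net = net, cache = list(b1 = b1$cache, ba = ba$cache, bb = bb$cache))
}

.body_bwd <- function(net, cache, dh1, grads) {
  ra <- .block_bwd(net, "res_a", cache$ba, dh1, grads); grads <- ra$grads
  rb <- .block_bwd(net, "res_b", cache$bb, dh1, grads); grads <- rb$grads
  d1 <- dh1 + ra$dx + rb$dx                       # skip connection
  r1 <- .block_bwd(net, "lin1", cache$b1, d1, grads)
  list(dx = r1$dx, grads = r1$grads)
}

.LOGVAR_CLAMP <- 15

# Encoder forward: x -> (mu, log_var). log_var is clamped to +/- .LOGVAR_CLAMP
# before exp() for numerical stability; the clamp mask is kept for backward.
.encoder_fwd <- function(net, x, training = FALSE) {
  stopifnot(net$kind == "encoder")
  if (ncol(x) != net$d_in) stop(sprintf("input width %d does not match encoder width %d",
                                        ncol(x), net$d_in))
  body <- .body_fwd(net, x, training)
  mu <- .linear_fwd(net$layers$head_mu, body$h1)
  lv <- .linear_fwd(net$layers$head_lv, body$h1)
  lv_clamped <- pmin(pmax(lv$out, -.LOGVAR_CLAMP), .LOGVAR_CLAMP)
  list(mu = mu$out, log_var = lv_clamped, net = body$net,
       cache = list(body = body$cache, mu = mu, lv = lv,
                    clamp_mask = abs(lv$out) < .LOGVAR_CLAMP))
}

.encoder_bwd <- function(net, cache, dmu, dlv) {
  grads <- .zero_grads(net)
  dlv <- dlv * cache$clamp_mask
  gm <- .linear_bwd(net$layers$head_mu, cache$mu, dmu)
  gl <- .linear_bwd(net$layers$head_lv, cache$lv, dlv)
  grads$head_mu$W <- gm$dW; grads$head_mu$b <- gm$db
  grads$head_lv$W <- gl$dW; grads$head_lv$b <- gl$db
  dh1 <- gm$dx + gl$dx
  .body_bwd(net, cache$body, dh1, grads)
}

.decoder_fwd <- function(net, z, training = FALSE) {
  stopifnot(net$kind == "decoder")
  if (ncol(z) != net$d_in) stop(sprintf("latent width %d does not match decoder width %d",
                                        ncol(z), net$d_in))
  body <- .body_fwd(net, z, training)
  out <- .linear_fwd(net$layers$head_out, body$h1)
  list(out = out$out, net = body$net, cache = list(body = body$cache, out = out))
}

.decoder_bwd <- function(net, cache, dout) {
  grads <- .zero_grads(net)
  go <- .linear_bwd(net$layers$head_out, cache$out, dout)
  grads$head_out$W <- go$dW; grads$head_out$b <- go$db
  .body_bwd(net, cache$body, go$dx, grads)
}

.zero_grads <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
    else list(gamma = numeric(length(l$gamma)), beta = numeric(length(l$beta)))
  })
}

.add_grads <- function(g1, g2) {
  for (nm in names(g2)) for (f in names(g2[[nm]])) {
    g1[[nm]][[f]] <- g1[[nm]][[f]] + g2[[nm]][[f]]
  }
  g1
}

# ---- AdamW ----------------------------------------------------------------

# Decoupled weight decay is applied to linear weight matrices only (not to
# biases or batchnorm scale/shift), the usual convention.
.adamw_new <- function(lr = 4e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-4) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L, state = list())
}

# nets: named list of dense_net; grads: matching named list of grad lists.
.adamw_step <- function(opt, nets, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (net_nm in names(nets)) {
    for (lay_nm in names(grads[[net_nm]])) {
      for (par_nm in names(grads[[net_nm]][[lay_nm]])) {
        g <- grads[[net_nm]][[lay_nm]][[par_nm]]
        key <- paste(net_nm, lay_nm, par_nm, sep = ".")
        st <- opt$state[[key]]
        if (is.null(st)) st <- list(m = g * 0, v = g * 0)
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
        opt$state[[key]] <- st
        p <- nets[[net_nm]]$layers[[lay_nm]][[par_nm]]
        upd <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
        if (par_nm == "W") upd <- upd + opt$weight_decay * p
        nets[[net_nm]]$layers[[lay_nm]][[par_nm]] <- p - opt$lr * upd
      }
    }
  }
  list(opt = opt, nets = nets)
}

# flatten/unflatten parameters (used by gradient checks and checkpoints)
.net_params_flat <- function(net) {
  out <- list()
  for (lay_nm in names(net$layers)) {
    l <- net$layers[[lay_nm]]
    for (par_nm in intersect(names(l), c("W", "b", "gamma", "beta"))) {
      out[[paste(lay_nm, par_nm, sep = ".")]] <- l[[par_nm]]
    }
  }
  out
}
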