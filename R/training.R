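#' Training configuration
#'
#' Defaults follow the published optimization protocol: AdamW with learning
#' rate 4e-4, mini-batches of 256 samples (capped at the training-set size),
#' at most 200 epochs, early stopping when the early-stop split's total loss
#' fails to improve for 10 consecutive epochs.
#'
#' @param learning_rate AdamW learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum epochs.
#' @param patience Consecutive non-improving epochs tolerated before stopping.
#' @param seed Master seed controlling initialization, shuffling and noise.
#' @param weights A [loss_weights()].
#' @param min_delta Improvement below this counts as no improvement.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 4e-4, batch_size = 256L,
                         max_epochs = 200L, patience = 10L, seed = 1L,
                         weights = loss_weights(), min_delta = 0) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed), weights = weights, min_delta = min_delta),
            class = "train_config")
}

#' Re-initialize a model's weights (Xavier/Glorot), deterministically
#'
#' All linear weights are redrawn Xavier-uniform, biases reset to zero, and
#' batchnorm statistics reset, from the given seed.
#'
#' @param model A `jvae`.
#' @param seed Integer seed.
#' @return The re-initialized model.
#' @export
initialize_weights <- function(model, seed) {
  stopifnot(inherits(model, "jvae"))
  jvae_new(model$config, model$weights, model$kernel, seed = seed,
           probes_a = model$probes_a, probes_b = model$probes_b)
}

.deep_copy_nets <- function(nets) rapply(nets, identity, how = "replace")

#' Train the joint VAE
#'
#' Optimizes the weighted total loss with AdamW on the training split,
#' evaluating the deterministic (posterior-mean, eval-mode) total loss on the
#' training and early-stop splits after every epoch. Stops at `max_epochs` or
#' after `patience` consecutive epochs without early-stop improvement, and
#' returns the weights of the best early-stop epoch. Mini-batch order and
#' reparameterization noise are reseeded per epoch from the master seed, so a
#' run is fully reproducible.
#'
#' @param model A `jvae` whose widths match the data.
#' @param data A `paired_platforms` object with standardized matrices.
#' @param splits A `split_assignment` over `data`'s rows; `train` is used for
#'   optimization and `early_stop` for the stopping rule (falls back to the
#'   training split, with a warning, if empty).
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best-epoch weights) and `history` (a
#'   `train_history`: data.frame of per-epoch loss components on both splits,
#'   `best_epoch`, `stop_reason`).
#' @export
train_jvae <- function(model, data, splits, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "jvae"), inherits(data, "paired_platforms"),
            inherits(splits, "split_assignment"), inherits(config, "train_config"))
  model$weights <- config$weights
  x_a <- data$A; x_b <- data$B
  tr <- splits$train
  es <- splits$early_stop
  if (length(es) == 0L) {
    warning("empty early-stop split; stopping on the training loss")
    es <- tr
  }
  if (max(c(tr, es)) > nrow(x_a)) stop("split indices exceed the data")
  bs <- min(config$batch_size, length(tr))
  dz <- model$config$d_z
  opt <- .adamw_new(lr = config$learning_rate,
                    weight_decay = model$config$weight_decay)

  old <- .save_rng(); on.exit(.restore_rng(old))
  hist <- list()
  best <- list(loss = Inf, epoch = 0L, nets = .deep_copy_nets(model$nets))
  bad <- 0L
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(config$seed + 1000L * epoch)   # per-epoch reseed from master seed
    order <- sample(tr)
    starts <- seq(1L, length(order), by = bs)
    for (s in starts) {
      idx <- order[s:min(s + bs - 1L, length(order))]
      n <- length(idx)
      eps_a <- matrix(stats::rnorm(n * dz), n, dz)
      eps_b <- matrix(stats::rnorm(n * dz), n, dz)
      step <- .jvae_step(model, x_a[idx, , drop = FALSE], x_b[idx, , drop = FALSE],
                         eps_a, eps_b, training = TRUE)
      if (!is.finite(step$loss$total)) {
        comp <- unlist(step$loss)
        stop("non-finite loss at epoch ", epoch, "; components: ",
             paste(names(comp), signif(comp, 4), sep = "=", collapse = ", "))
      }
      model <- step$model
      upd <- .adamw_step(opt, model$nets, step$grads)
      opt <- upd$opt
      model$nets <- upd$nets
    }
    lt <- .jvae_eval_loss(model, x_a[tr, , drop = FALSE], x_b[tr, , drop = FALSE])
    le <- .jvae_eval_loss(model, x_a[es, , drop = FALSE], x_b[es, , drop = FALSE])
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_rec = lt$rec, train_cross = lt$cross,
                                train_kl = lt$kl, train_align = lt$align,
                                train_total = lt$total,
                                es_rec = le$rec, es_cross = le$cross,
                                es_kl = le$kl, es_align = le$align,
                                es_total = le$total)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  early-stop %.5f", epoch,
                      lt$total, le$total))
    }
    if (le$total < best$loss - config$min_delta) {
      best <- list(loss = le$total, epoch = epoch, nets = .deep_copy_nets(model$nets))
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) { stop_reason <- "early_stop"; break }
    }
  }
  model$nets <- best$nets
  history <- structure(list(epochs = do.call(rbind, hist),
                            best_epoch = best$epoch,
                            best_es_total = best$loss,
                            stop_reason = stop_reason,
                            seed = config$seed),
                       class = "train_history")
  list(model = model, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("train_history: %d epoch(s), best epoch %d (early-stop total %.5f), stopped by %s\n",
              nrow(x$epochs), x$best_epoch, x$best_es_total, x$stop_reason))
  invisible(x)
}

#' Hyperparameter search over the tuning split
#'
#' Evaluates candidate configurations by training on the training split (with
#' early stopping) and scoring on the tuning split, returning the best
#' candidate. The search engine is a seeded random search over the declared
#' space; passing a data.frame of explicit candidates (`grid`) turns it into
#' an exhaustive grid search.
#'
#' @param space Named list of candidate values, each entry either a length-2
#'   numeric range (sampled uniformly, log-uniformly for `learning_rate`) or a
#'   vector of discrete choices. Recognized names: `learning_rate`, `hidden`,
#'   `dropout`, `d_z`, `lambda_rec`, `lambda_cross`, `lambda_kl`,
#'   `lambda_align`.
#' @param data A `paired_platforms` (standardized).
#' @param splits A `split_assignment` with non-empty `tune` set.
#' @param budget Number of trials (>= 1).
#' @param seed Seed for candidate sampling and trial training.
#' @param objective `"total_loss"` (tuning-split weighted total, minimized) or
#'   `"imputation_r"` (tuning-split median feature-wise cross-imputation r
#'   over both directions, maximized).
#' @param base_config A [train_config()] supplying everything not searched.
#' @param grid Optional data.frame of explicit candidates overriding `space`.
#' @param max_epochs Epoch cap per trial.
#' @return List with `best` (list: `net_config`, `train_config`, `score`),
#'   `trials` (data.frame of all candidates and scores).
#' @export
tune_hyperparameters <- function(space, data, splits, budget = 10L, seed = 1L,
                                 objective = c("total_loss", "imputation_r"),
                                 base_config = train_config(),
                                 grid = NULL, max_epochs = 30L) {
  objective <- match.arg(objective)
  if (is.null(grid) && budget < 1L) stop("trial budget must be >= 1")
  stopifnot(length(splits$tune) > 0L)
  cands <- if (!is.null(grid)) as.data.frame(grid) else
    .sample_candidates(space, budget, seed)
  d_a <- ncol(data$A); d_b <- ncol(data$B)
  scores <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cand <- as.list(cands[i, , drop = FALSE])
    nc <- network_config(
      d_a, d_b,
      d_z = cand$d_z %||% 128L,
      hidden = cand$hidden %||% 512L,
      dropout = cand$dropout %||% 0.1)
    lw <- loss_weights(
      lambda_rec = cand$lambda_rec %||% 0.90,
      lambda_cross = cand$lambda_cross %||% 1.4,
      lambda_kl = cand$lambda_kl %||% 1.4e-4,
      lambda_align = cand$lambda_align %||% 1.9)
    trial_epochs <- min(max_epochs, base_config$max_epochs)
    tc <- train_config(learning_rate = cand$learning_rate %||% base_config$learning_rate,
                       batch_size = base_config$batch_size,
                       max_epochs = trial_epochs,
                       patience = min(base_config$patience, trial_epochs),
                       seed = seed + i, weights = lw)
    m <- jvae_new(nc, lw, seed = seed + i)
    fit <- train_jvae(m, data, splits, tc)
    tu <- splits$tune
    if (objective == "total_loss") {
      scores[i] <- .jvae_eval_loss(fit$model, data$A[tu, , drop = FALSE],
                                   data$B[tu, , drop = FALSE])$total
    } else {
      ra <- correlation_report(impute(fit$model, data$A[tu, , drop = FALSE], "A2B"),
                               data$B[tu, , drop = FALSE])$feature_median
      rb <- correlation_report(impute(fit$model, data$B[tu, , drop = FALSE], "B2A"),
                               data$A[tu, , drop = FALSE])$feature_median
      scores[i] <- -(ra + rb) / 2          # negated: lower is better below
    }
  }
  best_i <- which.min(scores)
  cands$score <- if (objective == "total_loss") scores else -scores
  best_cand <- as.list(cands[best_i, , drop = FALSE])
  list(best = list(candidate = best_cand,
                   net_config = network_config(d_a, d_b,
                                               d_z = best_cand$d_z %||% 128L,
                                               hidden = best_cand$hidden %||% 512L,
                                               dropout = best_cand$dropout %||% 0.1),
                   weights = loss_weights(best_cand$lambda_rec %||% 0.90,
                                          best_cand$lambda_cross %||% 1.4,
                                          best_cand$lambda_kl %||% 1.4e-4,
                                          best_cand$lambda_align %||% 1.9),
                   score = cands$score[best_i]),
       trials = cands)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

.sample_candidates <- function(space, budget, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  draw_one <- function(nm) {
    v <- space[[nm]]
    if (length(v) == 2L && is.numeric(v) && nm %in% c("learning_rate", "dropout",
                                                      "lambda_rec", "lambda_cross",
                                                      "lambda_kl", "lambda_align")) {
      if (nm == "learning_rate" || nm == "lambda_kl") {
        exp(stats::runif(budget, log(v[1L]), log(v[2L])))   # log-uniform
      } else stats::runif(budget, v[1L], v[2L])
    } else {
      v[sample.int(length(v), budget, replace = TRUE)]
    }
  }
  as.data.frame(stats::setNames(lapply(names(space), draw_one), names(space)))
}

#' Save / load a model checkpoint
#'
#' Weights and batchnorm statistics go into an RDS container; all
#' hyperparameters (network configuration, loss weights, kernel settings,
#' probe universes, format version) are duplicated in a human-readable JSON
#' sidecar (`<path>.json`). Reload reproduces eval-mode outputs bit-exactly.
#'
#' @param model A `jvae`.
#' @param path Checkpoint path (the sidecar gets `.json` appended).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "jvae"))
  sidecar <- list(format_version = 1L,
                  config = unclass(model$config),
                  weights = unclass(model$weights),
                  kernel = unclass(model$kernel),
                  seed = model$seed,
                  probes_a = model$probes_a, probes_b = model$probes_b)
  saveRDS(model, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `jvae`.
#' @export
load_checkpoint <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing checkpoint sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(as.integer(side$format_version), 1L)) {
    stop("unsupported checkpoint format version: ", side$format_version)
  }
  model <- readRDS(path)
  if (!inherits(model, "jvae")) stop("checkpoint does not contain a jvae model")
  # sidecar is authoritative metadata; verify it matches the container
  for (f in c("d_a", "d_b", "d_z", "hidden")) {
    if (!isTRUE(all.equal(as.integer(side$config[[f]]), model$config[[f]]))) {
      stop("checkpoint sidecar disagrees with container on ", f)
    }
  }
  model
}
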