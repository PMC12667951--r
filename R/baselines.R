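#' KNN imputer configuration
#'
#' The published benchmark used k = 15 for Olink -> SomaScan and k = 30 for
#' SomaScan -> Olink, chosen by 5-fold cross-validation.
#'
#' @param k Neighbor count (1 <= k <= training N).
#' @param h Positive Gaussian kernel bandwidth in source-space Euclidean
#'   distance units.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 15L, h = 1) {
  stopifnot(k >= 1, h > 0)
  structure(list(k = as.integer(k), h = h), class = "knn_config")
}

#' Gaussian-kernel k-nearest-neighbour imputation
#'
#' For each query, finds the k nearest training samples in source space
#' (Euclidean) and imputes the target profile as their Gaussian-kernel
#' weighted average: `w_j = exp(-d_j^2 / (2 h^2))`; if all weights underflow
#' to zero the k neighbors are averaged uniformly.
#'
#' @param x_query Standardized query matrix (samples x source width).
#' @param train_source,train_target Standardized paired training matrices.
#' @param config A [knn_config()].
#' @return Imputed target matrix (query samples x target width).
#' @export
knn_impute <- function(x_query, train_source, train_target, config = knn_config()) {
  stopifnot(ncol(x_query) == ncol(train_source),
            nrow(train_source) == nrow(train_target))
  if (config$k > nrow(train_source)) {
    stop(sprintf("k = %d exceeds training size %d", config$k, nrow(train_source)))
  }
  d2 <- .sq_dists(x_query, train_source)
  out <- matrix(0, nrow(x_query), ncol(train_target),
                dimnames = list(rownames(x_query), colnames(train_target)))
  for (i in seq_len(nrow(x_query))) {
    nn <- order(d2[i, ])[seq_len(config$k)]
    w <- exp(-d2[i, nn] / (2 * config$h^2))
    if (sum(w) <= 0) w <- rep(1, config$k)      # uniform fallback
    out[i, ] <- crossprod(train_target[nn, , drop = FALSE], w) / sum(w)
  }
  out
}

#' Cross-validated selection of KNN hyperparameters
#'
#' 5-fold cross-validation over a (k, h) grid, selecting the pair that
#' maximizes the mean across folds of the held-fold median feature-wise
#' Pearson r. The default bandwidth grid is {0.5, 1, 2, 4} times the median
#' pairwise source-space distance.
#'
#' @param train_source,train_target Standardized paired training matrices.
#' @param k_grid Candidate neighbor counts.
#' @param h_grid Candidate bandwidths; `NULL` uses the median-distance grid.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return The selected [knn_config()]; attribute `cv` holds the score table.
#' @export
knn_cv <- function(train_source, train_target, k_grid = c(5L, 15L, 30L),
                   h_grid = NULL, folds = 5L, seed = 1L) {
  n <- nrow(train_source)
  stopifnot(n >= folds)
  if (is.null(h_grid)) {
    med <- stats::median(stats::dist(train_source[seq_len(min(n, 500L)), , drop = FALSE]))
    h_grid <- c(0.5, 1, 2, 4) * med
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(k = k_grid, h = h_grid)
  grid$score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    if (grid$k[g] > n - max(table(fold_id))) next
    sc <- numeric(folds)
    for (f in seq_len(folds)) {
      held <- fold_id == f
      imp <- knn_impute(train_source[held, , drop = FALSE],
                        train_source[!held, , drop = FALSE],
                        train_target[!held, , drop = FALSE],
                        knn_config(grid$k[g], grid$h[g]))
      sc[f] <- correlation_report(imp, train_target[held, , drop = FALSE])$feature_median
    }
    grid$score[g] <- mean(sc)
  }
  if (all(is.na(grid$score))) stop("no feasible (k, h) candidate")
  best <- which.max(grid$score)
  out <- knn_config(grid$k[best], grid$h[best])
  attr(out, "cv") <- grid
  out
}

#' WNN / supervised-PCA imputer configuration
#'
#' @param n_pcs Principal components per modality (default 100; lowered with a
#'   warning when the training size is insufficient).
#' @param union_neighbors Candidate neighbors gathered from each modality
#'   before refinement (default 400).
#' @param core_neighbors Neighbors kept per sample in the refined weighted
#'   graph (default 40).
#' @param reg Regularization added in weight denominators (default 1e-5).
#' @param regressor_neighbors Neighbors used by the final Gaussian-kernel
#'   regressor in sPCA space (default 50).
#' @param knn_weights Neighbors used when estimating per-sample modality
#'   weights (default 20).
#' @return A `wnn_config` list.
#' @export
wnn_config <- function(n_pcs = 100L, union_neighbors = 400L, core_neighbors = 40L,
                       reg = 1e-5, regressor_neighbors = 50L, knn_weights = 20L) {
  stopifnot(core_neighbors <= union_neighbors, n_pcs >= 1, reg > 0,
            regressor_neighbors >= 1, knn_weights >= 1)
  structure(list(n_pcs = as.integer(n_pcs),
                 union_neighbors = as.integer(union_neighbors),
                 core_neighbors = as.integer(core_neighbors), reg = reg,
                 regressor_neighbors = as.integer(regressor_neighbors),
                 knn_weights = as.integer(knn_weights)),
            class = "wnn_config")
}

# k nearest neighbors (excluding self when self_in_rows) from a squared
# distance matrix; returns index matrix n x k
.knn_index <- function(d2, k, exclude_self = FALSE) {
  n <- nrow(d2)
  t(vapply(seq_len(n), function(i) {
    o <- order(d2[i, ])
    if (exclude_self) o <- o[o != i]
    o[seq_len(k)]
  }, integer(k)))
}

#' Fit the weighted-nearest-neighbour supervised-PCA imputer
#'
#' The four-step pipeline: (1) standard PCA on each platform's scaled training
#' data; (2) per-sample modality weights from cross-modality neighborhood
#' predictive power — for each modality the distance between a sample's
#' embedding and the average embedding of its neighbors chosen within the same
#' modality (within affinity) versus neighbors chosen in the other modality
#' (cross affinity); exponential affinities form regularized ratio scores that
#' a softmax turns into weights — then a weighted similarity graph built from
#' a union of `union_neighbors` candidates per modality, refined to
#' `core_neighbors` per sample and row-normalized (rows sum to one after the
#' regularized normalization); (3) PCA of the graph-smoothed training data
#' yields a supervised-PCA basis per platform; (4) a Gaussian-kernel regressor
#' over `regressor_neighbors` nearest training samples in source sPCA space
#' predicts target-platform values.
#'
#' @param train_a,train_b Standardized paired training matrices.
#' @param config A [wnn_config()].
#' @return A `wnn_imputer` with PCA bases, modality weights, the smoothing
#'   graph, sPCA bases and the training embeddings/targets for both directions.
#' @export
wnn_fit <- function(train_a, train_b, config = wnn_config()) {
  stopifnot(nrow(train_a) == nrow(train_b))
  n <- nrow(train_a)
  n_pcs <- config$n_pcs
  max_pcs <- min(n - 1L, ncol(train_a), ncol(train_b))
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs lowered from %d to %d (training size/width limit)",
                    n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pca_a <- stats::prcomp(train_a, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pca_b <- stats::prcomp(train_b, center = TRUE, scale. = FALSE, rank. = n_pcs)
  if (any(pca_a$sdev[seq_len(min(2L, n_pcs))] <= 1e-12) ||
      any(pca_b$sdev[seq_len(min(2L, n_pcs))] <= 1e-12)) {
    stop("degenerate PCA: zero variance in leading components")
  }
  emb_a <- pca_a$x; emb_b <- pca_b$x

  d2a <- .sq_dists(emb_a, emb_a); d2b <- .sq_dists(emb_b, emb_b)
  kw <- min(config$knn_weights, n - 1L)
  nn_a <- .knn_index(d2a, kw, exclude_self = TRUE)
  nn_b <- .knn_index(d2b, kw, exclude_self = TRUE)

  # within- and cross-modality neighborhood predictions of each embedding
  pred <- function(emb, nn) {
    t(vapply(seq_len(n), function(i) colMeans(emb[nn[i, ], , drop = FALSE]),
             numeric(ncol(emb))))
  }
  d_within_a <- sqrt(rowSums((emb_a - pred(emb_a, nn_a))^2))
  d_cross_a <- sqrt(rowSums((emb_a - pred(emb_a, nn_b))^2))   # B-neighbors predicting A
  d_within_b <- sqrt(rowSums((emb_b - pred(emb_b, nn_b))^2))
  d_cross_b <- sqrt(rowSums((emb_b - pred(emb_b, nn_a))^2))

  # exponential affinities on per-sample scale; ratio score per modality
  scale_a <- stats::median(d_within_a) + config$reg
  scale_b <- stats::median(d_within_b) + config$reg
  ratio_a <- (exp(-d_within_a / scale_a) + config$reg) /
    (exp(-d_cross_a / scale_a) + config$reg)
  ratio_b <- (exp(-d_within_b / scale_b) + config$reg) /
    (exp(-d_cross_b / scale_b) + config$reg)
  ea <- exp(ratio_a); eb <- exp(ratio_b)
  w_a <- ea / (ea + eb)                       # softmax over the two modalities
  w_b <- 1 - w_a

  # weighted similarity graph over the union of per-modality candidates
  ku <- min(config$union_neighbors, n - 1L)
  kc <- min(config$core_neighbors, n)
  cand_a <- .knn_index(d2a, ku, exclude_self = TRUE)
  cand_b <- .knn_index(d2b, ku, exclude_self = TRUE)
  sig_a <- apply(d2a, 1L, function(r) sqrt(sort(r)[kw + 1L])) + config$reg
  sig_b <- apply(d2b, 1L, function(r) sqrt(sort(r)[kw + 1L])) + config$reg
  smooth_i <- matrix(0L, n, kc)
  smooth_w <- matrix(0, n, kc)
  for (i in seq_len(n)) {
    cand <- union(i, union(cand_a[i, ], cand_b[i, ]))   # self-edge included
    sim <- w_a[i] * exp(-sqrt(d2a[i, cand]) / sig_a[i]) +
      w_b[i] * exp(-sqrt(d2b[i, cand]) / sig_b[i])
    top <- cand[order(sim, decreasing = TRUE)[seq_len(min(kc, length(cand)))]]
    sw <- w_a[i] * exp(-sqrt(d2a[i, top]) / sig_a[i]) +
      w_b[i] * exp(-sqrt(d2b[i, top]) / sig_b[i]) + config$reg
    smooth_i[i, seq_along(top)] <- top
    smooth_w[i, seq_along(top)] <- sw / sum(sw)          # rows sum to 1 exactly
  }

  smooth <- function(x) {
    out <- matrix(0, n, ncol(x))
    for (i in seq_len(n)) {
      idx <- smooth_i[i, smooth_i[i, ] > 0L]
      out[i, ] <- crossprod(x[idx, , drop = FALSE], smooth_w[i, seq_along(idx)])
    }
    out
  }
  spca_a <- stats::prcomp(smooth(train_a), center = TRUE, scale. = FALSE, rank. = n_pcs)
  spca_b <- stats::prcomp(smooth(train_b), center = TRUE, scale. = FALSE, rank. = n_pcs)

  proj <- function(x, spca) sweep(x, 2L, spca$center, "-") %*% spca$rotation
  structure(list(config = config, n_pcs = n_pcs,
                 modality_weights = cbind(A = w_a, B = w_b),
                 smooth_index = smooth_i, smooth_weight = smooth_w,
                 spca_a = list(rotation = spca_a$rotation, center = spca_a$center),
                 spca_b = list(rotation = spca_b$rotation, center = spca_b$center),
                 train_emb_a = proj(train_a, spca_a),
                 train_emb_b = proj(train_b, spca_b),
                 train_a = train_a, train_b = train_b,
                 probes_a = colnames(train_a), probes_b = colnames(train_b)),
            class = "wnn_imputer")
}

#' Impute with a fitted WNN/sPCA imputer
#'
#' Projects queries into the source platform's sPCA space and predicts the
#' target platform as the Gaussian-kernel weighted average of the
#' `regressor_neighbors` nearest training samples; the kernel bandwidth is the
#' median training distance to the last used neighbor.
#'
#' @param fit A `wnn_imputer` from [wnn_fit()].
#' @param x_query Standardized source-platform query matrix.
#' @param direction `"A2B"` or `"B2A"`.
#' @param neighbors Override of the regressor neighbor count.
#' @return Imputed target matrix.
#' @export
wnn_impute <- function(fit, x_query, direction, neighbors = NULL) {
  stopifnot(inherits(fit, "wnn_imputer"))
  dir <- .parse_direction(direction)
  spca <- if (dir$src == "A") fit$spca_a else fit$spca_b
  tr_emb <- if (dir$src == "A") fit$train_emb_a else fit$train_emb_b
  tr_tgt <- if (dir$tgt == "A") fit$train_a else fit$train_b
  k <- min(neighbors %||% fit$config$regressor_neighbors, nrow(tr_emb))
  q_emb <- sweep(x_query, 2L, spca$center, "-") %*% spca$rotation
  d2 <- .sq_dists(q_emb, tr_emb)
  kth <- apply(d2, 1L, function(r) sqrt(sort(r)[k]))
  h <- stats::median(kth) + fit$config$reg
  out <- matrix(0, nrow(x_query), ncol(tr_tgt),
                dimnames = list(rownames(x_query), colnames(tr_tgt)))
  for (i in seq_len(nrow(x_query))) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- exp(-d2[i, nn] / (2 * h^2))
    if (sum(w) <= 0) w <- rep(1, k)
    out[i, ] <- crossprod(tr_tgt[nn, , drop = FALSE], w) / sum(w)
  }
  out
}

#' Permuted negative control
#'
#' Permutes platform B's sample-to-data mapping with a seeded permutation,
#' destroying cross-platform dependence while preserving each modality's
#' covariance structure exactly. Platform A is untouched.
#'
#' @param data A `paired_platforms`.
#' @param seed Integer seed.
#' @param permutation Optional explicit permutation of `1:N` overriding the
#'   seeded draw (the identity permutation leaves the object unchanged).
#' @return A `paired_platforms` with permuted B rows; the permutation is
#'   stored in attribute `permutation`.
#' @export
permuted_control <- function(data, seed = 1L, permutation = NULL) {
  stopifnot(inherits(data, "paired_platforms"))
  n <- nrow(data$A)
  if (is.null(permutation)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    permutation <- sample.int(n)
  }
  stopifnot(length(permutation) == n, all(sort(permutation) == seq_len(n)))
  b <- data$B[permutation, , drop = FALSE]
  rownames(b) <- rownames(data$B)               # mapping permuted, IDs kept
  out <- paired_platforms(data$A, b, probe_map = data$probe_map)
  attr(out, "permutation") <- permutation
  out
}
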