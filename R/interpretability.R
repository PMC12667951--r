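# Gradient of the posterior-mean cross-imputation map out = dec_tgt(enc_src(x)$mu)
# with respect to the input, for a given output-side gradient `dout` (N x d_tgt).
.impute_input_grad <- function(model, x, direction, dout) {
  dir <- .parse_direction(direction)
  enc <- model$nets[[paste0("enc_", tolower(dir$src))]]
  dec <- model$nets[[paste0("dec_", tolower(dir$tgt))]]
  ef <- .encoder_fwd(enc, x, training = FALSE)
  df <- .decoder_fwd(dec, ef$mu, training = FALSE)
  dz <- .decoder_bwd(dec, df$cache, dout)$dx
  zero <- matrix(0, nrow(x), ncol(dz))
  list(dx = .encoder_bwd(enc, ef$cache, dz, zero)$dx, out = df$out)
}

#' Feature-attribution importance matrix for one imputation direction
#'
#' For every one-to-one mapped output probe p, attributes the posterior-mean
#' cross-imputation output to each mapped input probe q per background sample,
#' then aggregates as the mean absolute attribution across samples. Both axes
#' are restricted to the one-to-one probe map, ordered so that row i and
#' column i refer to the same protein (diagonal = self-importance).
#'
#' Methods: `"gradient_input"` (gradient times input minus baseline; equal to
#' DeepLIFT's rescale rule on affine networks), `"integrated_gradients"`
#' (Riemann average of gradients along the straight path from the baseline;
#' satisfies completeness), `"expected_gradients"` (gradient-SHAP style:
#' baselines drawn from the background data, uniform path positions).
#'
#' @param model Trained `jvae` with probe universes recorded.
#' @param background Standardized held-out samples (rows) used as the
#'   evaluation set.
#' @param direction `"A2B"` or `"B2A"`.
#' @param probe_map One-to-one probe correspondence (`probe_a`, `probe_b`).
#' @param method Attribution method (see above).
#' @param baseline Input baseline; default the zero vector, i.e. the cohort
#'   mean in standardized units.
#' @param steps Path steps for integrated gradients (default 32).
#' @param n_samples Baseline/path draws for expected gradients (default 16).
#' @param seed Seed for expected-gradients sampling.
#' @return An `importance_matrix`: list with `values` (mapped source probes x
#'   mapped target probes, non-negative), `direction`, `method`, `probe_map`,
#'   and the aggregation rule in `aggregation`.
#' @export
importance_matrix <- function(model, background, direction, probe_map,
                              method = c("gradient_input", "integrated_gradients",
                                         "expected_gradients"),
                              baseline = NULL, steps = 32L, n_samples = 16L,
                              seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "jvae"), is.matrix(background))
  probe_map <- as.data.frame(probe_map)
  if (nrow(probe_map) == 0L) stop("empty probe_map: importance axes undefined")
  dir <- .parse_direction(direction)
  src_probes <- if (dir$src == "A") model$probes_a else model$probes_b
  tgt_probes <- if (dir$tgt == "A") model$probes_a else model$probes_b
  map_src <- if (dir$src == "A") probe_map$probe_a else probe_map$probe_b
  map_tgt <- if (dir$tgt == "A") probe_map$probe_a else probe_map$probe_b
  stopifnot(all(map_src %in% src_probes), all(map_tgt %in% tgt_probes))
  x <- background
  if (!is.null(colnames(x))) x <- x[, src_probes, drop = FALSE]
  n <- nrow(x); d_src <- ncol(x); d_tgt <- length(tgt_probes)
  if (is.null(baseline)) baseline <- numeric(d_src)
  base_mat <- matrix(baseline, n, d_src, byrow = TRUE)
  tgt_idx <- match(map_tgt, tgt_probes)
  src_idx <- match(map_src, src_probes)

  e_out <- function(j) { m <- matrix(0, n, d_tgt); m[, j] <- 1; m }
  vals <- matrix(0, length(src_idx), length(tgt_idx),
                 dimnames = list(map_src, map_tgt))

  if (method == "gradient_input") {
    for (jj in seq_along(tgt_idx)) {
      g <- .impute_input_grad(model, x, direction, e_out(tgt_idx[jj]))$dx
      attr_j <- g * (x - base_mat)
      vals[, jj] <- colMeans(abs(attr_j))[src_idx]
    }
  } else if (method == "integrated_gradients") {
    diffs <- x - base_mat
    acc <- vector("list", length(tgt_idx))
    for (jj in seq_along(tgt_idx)) acc[[jj]] <- matrix(0, n, d_src)
    alphas <- (seq_len(steps) - 0.5) / steps      # midpoint rule
    for (a in alphas) {
      xt <- base_mat + a * diffs
      for (jj in seq_along(tgt_idx)) {
        acc[[jj]] <- acc[[jj]] + .impute_input_grad(model, xt, direction,
                                                    e_out(tgt_idx[jj]))$dx
      }
    }
    for (jj in seq_along(tgt_idx)) {
      attr_j <- diffs * acc[[jj]] / steps
      vals[, jj] <- colMeans(abs(attr_j))[src_idx]
    }
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    acc <- vector("list", length(tgt_idx))
    for (jj in seq_along(tgt_idx)) acc[[jj]] <- matrix(0, n, d_src)
    for (s in seq_len(n_samples)) {
      b <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
      a <- stats::runif(1)
      xt <- b + a * (x - b)
      for (jj in seq_along(tgt_idx)) {
        g <- .impute_input_grad(model, xt, direction, e_out(tgt_idx[jj]))$dx
        acc[[jj]] <- acc[[jj]] + g * (x - b)
      }
    }
    for (jj in seq_along(tgt_idx)) {
      vals[, jj] <- colMeans(abs(acc[[jj]] / n_samples))[src_idx]
    }
  }
  structure(list(values = vals, direction = toupper(paste0(dir$src, "2", dir$tgt)),
                 method = method, probe_map = probe_map,
                 aggregation = "mean absolute per-sample attribution",
                 baseline = baseline, n_background = n),
            class = "importance_matrix")
}

#' Per-sample attribution with completeness bookkeeping
#'
#' Integrated-gradients attributions for a single output probe, returned per
#' sample together with `f(x) - f(baseline)` so completeness can be checked.
#'
#' @inheritParams importance_matrix
#' @param output_probe Target probe ID (or index).
#' @return List with `attributions` (N x d_src), `delta` (N vector of
#'   `f(x) - f(baseline)`).
#' @export
attribution_completeness <- function(model, background, direction, output_probe,
                                     baseline = NULL, steps = 64L) {
  dir <- .parse_direction(direction)
  tgt_probes <- if (dir$tgt == "A") model$probes_a else model$probes_b
  j <- if (is.character(output_probe)) match(output_probe, tgt_probes) else output_probe
  if (is.na(j)) stop("unknown output probe: ", output_probe)
  x <- background
  n <- nrow(x); d_src <- ncol(x)
  if (is.null(baseline)) baseline <- numeric(d_src)
  base_mat <- matrix(baseline, n, d_src, byrow = TRUE)
  diffs <- x - base_mat
  d_tgt <- if (dir$tgt == "A") model$config$d_a else model$config$d_b
  dout <- matrix(0, n, d_tgt)
  dout[, j] <- 1
  grad_sum <- matrix(0, n, d_src)
  alphas <- (seq_len(steps) - 0.5) / steps
  for (a in alphas) {
    grad_sum <- grad_sum + .impute_input_grad(model, base_mat + a * diffs,
                                              direction, dout)$dx
  }
  attr <- diffs * grad_sum / steps
  f_x <- impute(model, x, paste0(dir$src, "2", dir$tgt))[, j]
  f_b <- impute(model, base_mat[1L, , drop = FALSE], paste0(dir$src, "2", dir$tgt))[, j]
  list(attributions = attr, delta = f_x - f_b)
}

#' Split an importance matrix into self- and cross-importance
#'
#' The diagonal (read through the probe map: same protein on both platforms)
#' is the self-importance; the off-diagonal entries, both directions retained,
#' are the cross-importance.
#'
#' @param imp An `importance_matrix`.
#' @return List with `self` (named vector over mapped probes) and `cross`
#'   (the matrix with the diagonal set to `NA`).
#' @export
self_cross_split <- function(imp) {
  stopifnot(inherits(imp, "importance_matrix"))
  v <- imp$values
  stopifnot(nrow(v) == ncol(v))
  self <- diag(v)
  names(self) <- rownames(v)
  cross <- v
  diag(cross) <- NA_real_
  list(self = self, cross = cross)
}

.family_of <- function(ids, family_regex = "[0-9]+$") sub(family_regex, "", ids)

#' Symmetric pair scores from the two directional importance matrices
#'
#' For each unordered mapped-probe pair (p, q) takes the maximum importance
#' over both directions and both orders. With `family_regex` set, probes
#' sharing a prefix (default: the ID with trailing digits stripped) are
#' treated as one family and merged by the maximum.
#'
#' @param imp_ab,imp_ba `importance_matrix` objects for the two directions
#'   (either may be `NULL`).
#' @param family_regex Optional regex defining the shared-prefix family rule;
#'   `NULL` (default) disables grouping.
#' @return Symmetric matrix of pair scores (diagonal `NA`), rownames =
#'   mapped probe (or family) IDs.
#' @export
pair_importance <- function(imp_ab, imp_ba = NULL, family_regex = NULL) {
  mats <- Filter(Negate(is.null), list(imp_ab, imp_ba))
  stopifnot(length(mats) >= 1L)
  vals <- lapply(mats, function(m) {
    stopifnot(inherits(m, "importance_matrix"))
    v <- abs(m$values)
    pmax(v, t(v))                                 # max over both orders
  })
  s <- Reduce(pmax, vals)                         # max over both directions
  ids <- rownames(mats[[1L]]$values)
  dimnames(s) <- list(ids, ids)
  diag(s) <- NA_real_
  if (!is.null(family_regex)) {
    fam <- .family_of(ids, family_regex)
    ufam <- unique(fam)
    out <- matrix(NA_real_, length(ufam), length(ufam), dimnames = list(ufam, ufam))
    for (i in seq_along(ufam)) for (j in seq_len(i - 1L)) {
      block <- s[fam == ufam[i], fam == ufam[j], drop = FALSE]
      out[i, j] <- out[j, i] <- max(block, na.rm = TRUE)
    }
    s <- out
  }
  s
}

#' Reference edge set for enrichment analysis
#'
#' Normalizes a two/three-column edge table (STRING-style) into undirected,
#' deduplicated edges restricted to a probe universe, with self-edges removed.
#'
#' @param edges Data frame/matrix; first two columns are probe IDs, optional
#'   third column a score.
#' @param probes Probe universe (edges outside it are dropped).
#' @param channel Evidence tag (`"association"` or `"physical"`).
#' @return A `reference_edges` data.frame with columns `probe1`, `probe2`
#'   (lexicographically ordered within a row) and optional `score`.
#' @export
reference_edges <- function(edges, probes, channel = c("association", "physical")) {
  channel <- match.arg(channel)
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  score <- if (ncol(e) >= 3L) as.numeric(e[[3L]]) else NULL
  a <- as.character(e[[1L]]); b <- as.character(e[[2L]])
  keep <- a %in% probes & b %in% probes & a != b   # self-interactions removed
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(probe1 = lo, probe2 = hi, stringsAsFactors = FALSE)
  if (!is.null(score)) out$score <- score[keep]
  out <- out[!duplicated(paste(out$probe1, out$probe2, sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channel") <- channel
  class(out) <- c("reference_edges", "data.frame")
  out
}

# upper-triangle pair universe of a symmetric score matrix
.pair_universe <- function(scores) {
  ids <- rownames(scores)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  data.frame(probe1 = pmin(ids[ut[, 1L]], ids[ut[, 2L]]),
             probe2 = pmax(ids[ut[, 1L]], ids[ut[, 2L]]),
             score = scores[ut], stringsAsFactors = FALSE)
}

.auprc_from_labels <- function(score, positive, n_thresholds = 16L) {
  pos_scores <- score[score > 0]
  if (length(pos_scores) == 0L) pos_scores <- 1e-12
  hi <- max(score)
  lo <- min(pos_scores)                           # log-spacing floor: smallest positive
  if (hi <= lo) hi <- lo * (1 + 1e-9)
  thresholds <- exp(seq(log(hi), log(lo), length.out = n_thresholds))
  n_pos <- sum(positive)
  prec <- rec <- numeric(n_thresholds)
  for (t in seq_len(n_thresholds)) {
    pred <- score >= thresholds[t]
    np <- sum(pred)
    tp <- sum(pred & positive)
    prec[t] <- if (np > 0) tp / np else 1
    rec[t] <- tp / n_pos
  }
  # anchor at recall 0 with the most-stringent precision so the trapezoid is
  # well defined even when the tightest threshold already attains full recall
  rec_a <- c(0, rec); prec_a <- c(prec[1L], prec)
  o <- order(rec_a)
  auprc <- sum(diff(rec_a[o]) * (prec_a[o][-1L] + prec_a[o][-length(prec_a)]) / 2)
  list(precision = prec, recall = rec, thresholds = thresholds, auprc = auprc)
}

#' Precision-recall curve of pair scores against a reference edge set
#'
#' Thresholds are 16 logarithmically spaced values from the maximum observed
#' score down to the smallest positive score; at each, predicted edges are
#' pairs at or above the threshold, precision is the fraction of predicted
#' pairs in the reference, recall the fraction of reference edges predicted.
#' AUPRC is the trapezoidal integral over recall-sorted points.
#'
#' @param scores Symmetric pair-score matrix (from [pair_importance()]).
#' @param edges A [reference_edges()] set (>= 1 edge within the score
#'   universe).
#' @param n_thresholds Number of thresholds (default 16).
#' @return List: `precision`, `recall`, `thresholds`, `auprc`, `prevalence`.
#' @export
pr_curve <- function(scores, edges, n_thresholds = 16L) {
  uni <- .pair_universe(scores)
  key <- paste(uni$probe1, uni$probe2, sep = "\r")
  ek <- paste(edges$probe1, edges$probe2, sep = "\r")
  positive <- key %in% ek
  if (!any(positive)) stop("no reference edges inside the score universe")
  res <- .auprc_from_labels(uni$score, positive, n_thresholds)
  res$prevalence <- mean(positive)
  res
}

#' Permutation test of AUPRC enrichment
#'
#' Reference-membership labels are permuted over the candidate pair universe
#' (all unordered mapped-probe pairs, self-pairs excluded), keeping the
#' importance values and the positive count fixed; each permutation yields a
#' full PR curve and AUPRC. `p = (k + 1) / (n + 1)` where k counts null AUPRCs
#' at or above the observed one.
#'
#' @param scores Symmetric pair-score matrix.
#' @param edges A [reference_edges()] set.
#' @param n Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @param n_thresholds Thresholds per PR curve.
#' @return A `permutation_test_result`: list with `observed`, `null` (vector
#'   of n AUPRCs), `k`, `p`.
#' @export
permutation_test <- function(scores, edges, n = 1000L, seed = 1L,
                             n_thresholds = 16L) {
  uni <- .pair_universe(scores)
  key <- paste(uni$probe1, uni$probe2, sep = "\r")
  positive <- key %in% paste(edges$probe1, edges$probe2, sep = "\r")
  if (!any(positive)) stop("no reference edges inside the score universe")
  observed <- .auprc_from_labels(uni$score, positive, n_thresholds)$auprc
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null <- vapply(seq_len(n), function(i) {
    .auprc_from_labels(uni$score, sample(positive), n_thresholds)$auprc
  }, numeric(1))
  k <- sum(null >= observed)
  structure(list(observed = observed, null = null, k = k, n = n,
                 p = (k + 1) / (n + 1)),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("AUPRC %.4f vs permutation null (n=%d, mean %.4f): k=%d, p=%.4g\n",
              x$observed, x$n, mean(x$null), x$k, x$p))
  invisible(x)
}

#' Node-level importance summaries
#'
#' For every output probe, input probes are ranked by importance (rank 1 =
#' most important; ties get average ranks); a probe's node score is its mean
#' rank across outputs, so lower is more important. With a reference edge set,
#' also returns the cumulative edge-density enrichment over probes ordered by
#' node score.
#'
#' @param imp An `importance_matrix`.
#' @param edges Optional [reference_edges()] for the density curve.
#' @return List with `mean_rank` (named vector) and optionally `density`
#'   (data.frame `n_top`, `edge_density`).
#' @export
node_importance <- function(imp, edges = NULL) {
  stopifnot(inherits(imp, "importance_matrix"))
  v <- imp$values
  ranks <- apply(v, 2L, function(col) rank(-col, ties.method = "average"))
  mean_rank <- rowMeans(ranks)
  names(mean_rank) <- rownames(v)
  out <- list(mean_rank = mean_rank)
  if (!is.null(edges)) {
    ord <- names(sort(mean_rank))                  # most important first
    ek <- paste(edges$probe1, edges$probe2, sep = "\r")
    dens <- vapply(2:length(ord), function(j) {
      top <- ord[seq_len(j)]
      pairs <- utils::combn(sort(top), 2L)
      mean(paste(pairs[1L, ], pairs[2L, ], sep = "\r") %in% ek)
    }, numeric(1))
    out$density <- data.frame(n_top = 2:length(ord), edge_density = dens)
  }
  out
}

#' Correlate self-importance with measurement consistency and accuracy
#'
#' @param self Named self-importance vector (from [self_cross_split()]).
#' @param report A [correlation_report()] of the imputation (per-probe r).
#' @param measured_r Named vector of measured cross-platform per-probe r.
#' @return List with `r_vs_measured`, `r_vs_imputation` (Pearson r of
#'   self-importance against each).
#' @export
importance_vs_accuracy <- function(self, report, measured_r) {
  ids <- names(self)
  imp_r <- report$feature_r[ids]
  mr <- measured_r[ids]
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3L) stats::cor(a[ok], b[ok]) else NA_real_
  }
  list(r_vs_measured = safe_cor(self, mr),
       r_vs_imputation = safe_cor(self, imp_r))
}
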