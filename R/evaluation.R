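#' Pearson correlation with explicit degenerate handling
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Sample Pearson r, or `NA_real_` when either vector is constant
#'   (undefined correlations are excluded from distributions with a count, not
#'   set to zero).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("pearson_r needs length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Feature- and sample-wise correlation report
#'
#' Per-probe r across samples (the primary imputation accuracy metric) and
#' per-sample r across probes, with medians and means. Probes or samples with
#' undefined correlations (constant vectors) are excluded and counted.
#'
#' @param imputed,truth Matrices of identical shape (samples x probes).
#' @param method,direction Optional tags carried into the report.
#' @return A `correlation_report`: list with `feature_r`, `sample_r`,
#'   `feature_median`, `feature_mean`, `sample_median`, `sample_mean`,
#'   `n_undefined_features`, `n_undefined_samples`, `method`, `direction`.
#' @export
correlation_report <- function(imputed, truth, method = NA_character_,
                               direction = NA_character_) {
  stopifnot(all(dim(imputed) == dim(truth)))
  feature_r <- vapply(seq_len(ncol(truth)), function(j) {
    sx <- stats::sd(imputed[, j]); sy <- stats::sd(truth[, j])
    if (sx == 0 || sy == 0 || !is.finite(sx) || !is.finite(sy)) NA_real_
    else stats::cor(imputed[, j], truth[, j])
  }, numeric(1))
  names(feature_r) <- colnames(truth)
  sample_r <- vapply(seq_len(nrow(truth)), function(i) {
    sx <- stats::sd(imputed[i, ]); sy <- stats::sd(truth[i, ])
    if (sx == 0 || sy == 0 || !is.finite(sx) || !is.finite(sy)) NA_real_
    else stats::cor(imputed[i, ], truth[i, ])
  }, numeric(1))
  names(sample_r) <- rownames(truth)
  structure(list(feature_r = feature_r, sample_r = sample_r,
                 feature_median = stats::median(feature_r, na.rm = TRUE),
                 feature_mean = mean(feature_r, na.rm = TRUE),
                 sample_median = stats::median(sample_r, na.rm = TRUE),
                 sample_mean = mean(sample_r, na.rm = TRUE),
                 n_undefined_features = sum(is.na(feature_r)),
                 n_undefined_samples = sum(is.na(sample_r)),
                 method = method, direction = direction),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report%s: median feature r %.3f (mean %.3f, %d undefined); median sample r %.3f (mean %.3f, %d undefined)\n",
              if (is.na(x$method)) "" else paste0(" [", x$method, "]"),
              x$feature_median, x$feature_mean, x$n_undefined_features,
              x$sample_median, x$sample_mean, x$n_undefined_samples))
  invisible(x)
}

#' Compare two methods' correlation distributions
#'
#' Mann-Whitney U on the r distributions, a paired per-item win-rate two-tailed
#' binomial test, a Levene (Brown-Forsythe) variance test, and a Wilcoxon
#' signed-rank test for paired differences.
#'
#' @param report1,report2 `correlation_report` objects over the same items.
#' @param which `"feature"` or `"sample"` correlations.
#' @return List of `htest`-style results: `mann_whitney`, `binomial_wins`
#'   (wins counted for `report1`, ties dropped), `levene`, `wilcoxon_paired`,
#'   and the win counts.
#' @export
distribution_tests <- function(report1, report2, which = c("feature", "sample")) {
  which <- match.arg(which)
  r1 <- report1[[paste0(which, "_r")]]
  r2 <- report2[[paste0(which, "_r")]]
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  mwu <- stats::wilcox.test(r1, r2, exact = FALSE)
  wins <- sum(r1 > r2); losses <- sum(r1 < r2)
  binom <- stats::binom.test(wins, wins + losses, p = 0.5)
  lev <- .levene_test(c(r1, r2), rep(c("m1", "m2"), c(length(r1), length(r2))))
  wsr <- stats::wilcox.test(r1, r2, paired = TRUE, exact = FALSE)
  list(mann_whitney = mwu, binomial_wins = binom, levene = lev,
       wilcoxon_paired = wsr, wins = wins, losses = losses, n = length(r1))
}

# Brown-Forsythe variant (deviations from the group median), via car when
# available, otherwise the equivalent one-way ANOVA on absolute deviations.
.levene_test <- function(values, group) {
  group <- factor(group)
  if (requireNamespace("car", quietly = TRUE)) {
    res <- car::leveneTest(values, group, center = stats::median)
    return(list(statistic = res[1, "F value"], p.value = res[1, "Pr(>F)"],
                method = "Levene (car, median-centered)"))
  }
  dev <- abs(values - stats::ave(values, group, FUN = stats::median))
  fit <- stats::oneway.test(dev ~ group, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p.value = fit$p.value,
       method = "Levene (median-centered, one-way ANOVA)")
}

#' Per-probe mean/variance summary
#'
#' @param x Matrix (samples x probes).
#' @return Data frame with `probe`, `mean`, `variance` (sample variance).
#' @export
mean_variance_summary <- function(x) {
  data.frame(probe = colnames(x) %||% as.character(seq_len(ncol(x))),
             mean = colMeans(x),
             variance = apply(x, 2L, stats::var),
             row.names = NULL)
}

#' PCA diagnostics of imputed against measured data
#'
#' Fits PCA on the measured (truth) data only and projects each imputed matrix
#' onto the truth principal components, feature-wise (features as points,
#' colored by seeded k-means clusters of the measured feature profiles) and
#' sample-wise. Optionally projects pooled latent embeddings and their
#' paired-sample differences.
#'
#' @param truth Measured matrix (samples x probes).
#' @param imputed_list Named list of imputed matrices of the same shape.
#' @param k_clusters k for the k-means coloring (default 6).
#' @param n_pcs Components retained.
#' @param seed Seed for k-means.
#' @param latent_a,latent_b Optional paired latent embeddings for the latent
#'   variant.
#' @return List with `feature` (truth scores, imputed projections, cluster
#'   vector), `sample` (likewise), and optionally `latent` (pooled projection
#'   plus paired differences).
#' @export
pca_diagnostics <- function(truth, imputed_list, k_clusters = 6L, n_pcs = 2L,
                            seed = 1L, latent_a = NULL, latent_b = NULL) {
  stopifnot(is.list(imputed_list))
  old <- .save_rng(); on.exit(.restore_rng(old))
  proj_onto <- function(pca, x) sweep(x, 2L, pca$center, "-") %*% pca$rotation
  # feature-wise: features are points, profiles across samples are coordinates
  ft <- t(truth)
  pca_f <- stats::prcomp(ft, center = TRUE, scale. = FALSE, rank. = n_pcs)
  set.seed(seed)
  cl <- stats::kmeans(ft, centers = min(k_clusters, nrow(ft) - 1L), nstart = 5L)
  feature <- list(truth = pca_f$x,
                  imputed = lapply(imputed_list, function(m) proj_onto(pca_f, t(m))),
                  clusters = cl$cluster)
  pca_s <- stats::prcomp(truth, center = TRUE, scale. = FALSE, rank. = n_pcs)
  sample <- list(truth = pca_s$x,
                 imputed = lapply(imputed_list, function(m) proj_onto(pca_s, m)))
  out <- list(feature = feature, sample = sample)
  if (!is.null(latent_a) && !is.null(latent_b)) {
    pooled <- rbind(latent_a, latent_b)
    pca_z <- stats::prcomp(pooled, center = TRUE, scale. = FALSE, rank. = n_pcs)
    out$latent <- list(pooled = pca_z$x,
                       platform = rep(c("A", "B"), c(nrow(latent_a), nrow(latent_b))),
                       paired_diff = proj_onto(pca_z, latent_a) - proj_onto(pca_z, latent_b))
  }
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Hand-written step-up procedure exposed so the evaluation battery's FDR
#' machinery can itself be validated against a reference implementation
#' (`p.adjust(method = "BH")`) in the test suite.
#'
#' @param p Vector of p-values (NAs preserved).
#' @return Monotone q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0L) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  q <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok[o]] <- q
  out
}

#' Protein-phenotype association tests with sex/age adjustment
#'
#' Continuous phenotypes are residualized on sex and age, then regressed on
#' each standardized probe (simple linear model); binary phenotypes are fit
#' per probe by logistic regression with sex and age as covariates
#' (residualizing a binary outcome is ill-defined). Benjamini-Hochberg FDR is
#' controlled within each phenotype across probes by default, flagged at 5%.
#'
#' @param x Standardized protein matrix (samples x probes).
#' @param phenotypes Data frame with one column per phenotype plus covariate
#'   columns `sex` (0/1) and `age`.
#' @param types Named character vector typing each phenotype column
#'   (`"continuous"` or `"binary"`); covariate columns are skipped.
#' @param fdr_family `"per_phenotype"` (default) or `"global"`.
#' @return An `association_result` data.frame: `phenotype`, `probe`, `effect`
#'   (regression coefficient or log-odds ratio), `se`, `p`, `q`, `significant`
#'   (q <= 0.05).
#' @export
phenotype_associations <- function(x, phenotypes, types,
                                   fdr_family = c("per_phenotype", "global")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(is.matrix(x), nrow(x) == nrow(phenotypes),
            all(c("sex", "age") %in% colnames(phenotypes)))
  pheno_names <- names(types)
  stopifnot(all(pheno_names %in% colnames(phenotypes)))
  probes <- colnames(x) %||% as.character(seq_len(ncol(x)))
  sex <- phenotypes$sex; age <- phenotypes$age
  res <- vector("list", length(pheno_names))
  for (pi in seq_along(pheno_names)) {
    ph <- pheno_names[pi]
    y <- phenotypes[[ph]]
    type <- match.arg(types[[ph]], c("continuous", "binary"))
    if (type == "continuous") {
      if (length(unique(y)) < 3L) stop("phenotype '", ph, "' typed continuous has < 3 distinct values")
      yr <- stats::resid(stats::lm(y ~ sex + age))
      # vectorized simple OLS of residualized phenotype on each probe
      n <- length(yr)
      xc <- sweep(x, 2L, colMeans(x), "-")
      yc <- yr - mean(yr)
      sxx <- colSums(xc^2)
      beta <- as.numeric(crossprod(xc, yc)) / sxx
      alpha <- mean(yr) - beta * colMeans(x)
      rss <- sum(yc^2) - beta^2 * sxx             # residual SS of each fit
      df <- n - 2L
      se <- sqrt(pmax(rss, 0) / df / sxx)
      tval <- beta / se
      p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      res[[pi]] <- data.frame(phenotype = ph, probe = probes, effect = beta,
                              se = se, p = p, stringsAsFactors = FALSE)
    } else {
      eff <- se <- p <- numeric(ncol(x))
      for (j in seq_len(ncol(x))) {
        fit <- stats::glm(y ~ x[, j] + sex + age, family = stats::binomial())
        cf <- summary(fit)$coefficients
        eff[j] <- cf[2L, 1L]; se[j] <- cf[2L, 2L]; p[j] <- cf[2L, 4L]
      }
      res[[pi]] <- data.frame(phenotype = ph, probe = probes, effect = eff,
                              se = se, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (fdr_family == "per_phenotype") {
    out$q <- stats::ave(out$p, out$phenotype, FUN = bh_adjust)
  } else {
    out$q <- bh_adjust(out$p)
  }
  out$significant <- out$q <= 0.05
  class(out) <- c("association_result", "data.frame")
  out
}

#' Concordance between truth and imputed association results
#'
#' Mean absolute error of effect estimates over truth-significant pairs,
#' Pearson r of effects (split by phenotype type when given), and the recovery
#' rate `|truth-significant AND imputed-significant| / |truth-significant|`,
#' overall and stratified by each phenotype's truth-hit count.
#'
#' @param result_truth,result_imputed `association_result` data frames over
#'   the same (phenotype, probe) pairs.
#' @param types Optional named phenotype-type vector for type-split effect
#'   correlations.
#' @return List with `mae_significant`, `effect_r`, `effect_r_by_type`,
#'   `recovery`, `n_truth_significant`, `by_phenotype` (data.frame).
#' @export
association_concordance <- function(result_truth, result_imputed, types = NULL) {
  key <- function(d) paste(d$phenotype, d$probe, sep = "\r")
  stopifnot(setequal(key(result_truth), key(result_imputed)))
  result_imputed <- result_imputed[match(key(result_truth), key(result_imputed)), ]
  sig <- result_truth$significant
  mae <- if (any(sig)) mean(abs(result_truth$effect[sig] - result_imputed$effect[sig])) else NA_real_
  eff_r <- if (sum(sig) >= 3L) stats::cor(result_truth$effect[sig], result_imputed$effect[sig]) else NA_real_
  eff_by_type <- NULL
  if (!is.null(types)) {
    tv <- types[result_truth$phenotype]
    eff_by_type <- vapply(unique(tv), function(tt) {
      i <- sig & tv == tt
      if (sum(i) >= 3L) stats::cor(result_truth$effect[i], result_imputed$effect[i]) else NA_real_
    }, numeric(1))
  }
  recovered <- sig & result_imputed$significant
  by_ph <- do.call(rbind, lapply(split(seq_len(nrow(result_truth)), result_truth$phenotype),
                                 function(i) {
    data.frame(phenotype = result_truth$phenotype[i[1L]],
               truth_hits = sum(sig[i]),
               recovered = sum(recovered[i]),
               recovery = if (sum(sig[i]) > 0) sum(recovered[i]) / sum(sig[i]) else NA_real_)
  }))
  rownames(by_ph) <- NULL
  list(mae_significant = mae, effect_r = eff_r, effect_r_by_type = eff_by_type,
       recovery = if (any(sig)) sum(recovered) / sum(sig) else NA_real_,
       n_truth_significant = sum(sig), by_phenotype = by_ph)
}

#' Stouffer z-score combination
#'
#' @param z Vector (or matrix with studies in columns) of z-scores.
#' @param weights Optional study weights (defaults to equal).
#' @return Combined z: `sum(w z) / sqrt(sum(w^2))`.
#' @export
stouffer_z <- function(z, weights = NULL) {
  if (is.matrix(z)) {
    w <- weights %||% rep(1, ncol(z))
    as.numeric(z %*% w) / sqrt(sum(w^2))
  } else {
    w <- weights %||% rep(1, length(z))
    sum(w * z) / sqrt(sum(w^2))
  }
}

.assoc_z <- function(assoc) {
  # signed z from two-sided p, capped for p underflow
  p <- pmax(assoc$p, 1e-300)
  sign(assoc$effect) * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Mixed-platform meta-analysis workflows
#'
#' Simulates two-cohort meta-analysis where one cohort lacks the target
#' platform. Per replicate, samples are split into two pseudo-cohorts: cohort
#' 1 keeps its native target-platform data; cohort 2 keeps only the source
#' platform. Workflows compared against the truth (associations on the full
#' actual target data, 5% FDR):
#' \describe{
#'   \item{classic}{each cohort tested on its own native platform over the
#'     shared (mapped) probes; z-scores combined by Stouffer.}
#'   \item{imputation_separate}{cohort 2 imputed to the target platform,
#'     tested separately, z-combined with cohort 1.}
#'   \item{imputation_combined}{cohort 2 imputed then concatenated with cohort
#'     1 into one harmonized table, tested once.}
#' }
#'
#' @param source Full source-platform matrix (samples x source probes),
#'   standardized.
#' @param target Full native target-platform matrix (same samples),
#'   standardized; the truth associations are computed on it.
#' @param phenotypes,types As in [phenotype_associations()].
#' @param imputer Function `(x_source_rows) -> imputed target matrix` (e.g. a
#'   wrapper around [impute()], [knn_impute()] or an oracle).
#' @param probe_map Data frame (`probe_a` = source probe, `probe_b` = target
#'   probe) giving the shared probes the classic workflow can test; the
#'   analysis is restricted to mapped target probes.
#' @param n_replicates Number of random cohort splits (default 20).
#' @param seed Seed; replicate r uses `seed + r`.
#' @return A `meta_result` data.frame: one row per (replicate, workflow,
#'   phenotype) with `truth_hits`, `recovered`, `recovery`.
#' @export
meta_analysis <- function(source, target, phenotypes, types, imputer,
                          probe_map, n_replicates = 20L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  stopifnot(nrow(source) == nrow(target))
  probe_map <- as.data.frame(probe_map)
  tgt_probes <- probe_map$probe_b
  src_probes <- probe_map$probe_a
  stopifnot(all(tgt_probes %in% colnames(target)),
            all(src_probes %in% colnames(source)))
  tgt <- target[, tgt_probes, drop = FALSE]
  truth <- phenotype_associations(tgt, phenotypes, types)
  n <- nrow(source)
  out <- list()
  for (r in seq_len(n_replicates)) {
    old <- .save_rng()
    set.seed(seed + r)
    c1 <- sort(sample.int(n, floor(n / 2)))
    .restore_rng(old)
    c2 <- setdiff(seq_len(n), c1)

    assoc_sub <- function(mat, idx) {
      phenotype_associations(mat[idx, , drop = FALSE],
                             phenotypes[idx, , drop = FALSE], types)
    }
    combine <- function(a1, a2) {
      z <- cbind(.assoc_z(a1), .assoc_z(a2))
      zc <- stouffer_z(z)
      p <- 2 * stats::pnorm(abs(zc), lower.tail = FALSE)
      res <- a1
      res$effect <- (a1$effect + a2$effect) / 2
      res$p <- p
      res$q <- stats::ave(res$p, res$phenotype, FUN = bh_adjust)
      res$significant <- res$q <= 0.05
      res
    }

    # classic: cohort 1 native target; cohort 2 native source over mapped probes
    src_mapped <- source[, src_probes, drop = FALSE]
    colnames(src_mapped) <- tgt_probes          # align probe identity across platforms
    classic <- combine(assoc_sub(tgt, c1), assoc_sub(src_mapped, c2))

    imp2 <- imputer(source[c2, , drop = FALSE])[, tgt_probes, drop = FALSE]
    sep <- combine(assoc_sub(tgt, c1),
                   phenotype_associations(imp2, phenotypes[c2, , drop = FALSE], types))

    comb_mat <- rbind(tgt[c1, , drop = FALSE], imp2)
    comb_ph <- rbind(phenotypes[c1, , drop = FALSE], phenotypes[c2, , drop = FALSE])
    combined <- phenotype_associations(comb_mat, comb_ph, types)

    score <- function(workflow, assoc) {
      cc <- association_concordance(truth, assoc)
      cbind(replicate = r, workflow = workflow, cc$by_phenotype)
    }
    out[[length(out) + 1L]] <- rbind(score("classic", classic),
                                     score("imputation_separate", sep),
                                     score("imputation_combined", combined))
  }
  res <- do.call(rbind, out)
  class(res) <- c("meta_result", "data.frame")
  attr(res, "truth") <- truth
  res
}

#' Summarize meta-analysis recovery by workflow
#'
#' @param meta A `meta_result` from [meta_analysis()].
#' @param min_truth_hits Restrict to phenotypes with at least this many truth
#'   hits (default 1).
#' @return Data frame of mean recovery per workflow.
#' @export
meta_summary <- function(meta, min_truth_hits = 1L) {
  keep <- meta$truth_hits >= min_truth_hits
  agg <- stats::aggregate(recovery ~ workflow, data = meta[keep, , drop = FALSE],
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$workflow), , drop = FALSE]
}
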