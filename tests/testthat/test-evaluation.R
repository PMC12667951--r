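test_that("pearson_r handles exact, anti, and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_true(is.na(pearson_r(x, rep(2, 5))))
  expect_error(pearson_r(1:2, 2:3), "length")
  set.seed(60)
  a <- rnorm(30); b <- rnorm(30)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
})

test_that("correlation_report summarizes both axes and excludes undefined probes", {
  set.seed(61)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("s", 1:20), paste0("P", 1:10)))
  rep1 <- correlation_report(x, x)
  expect_equal(unname(rep1$feature_r), rep(1, 10), tolerance = 1e-12)
  expect_true(all(abs(rep1$sample_r - 1) < 1e-12))
  expect_equal(rep1$feature_median, 1)

  # permuted imputation decorrelates
  y <- x[sample(20), ]
  rep2 <- correlation_report(y, x)
  expect_lt(abs(rep2$feature_median), 0.5)

  # simultaneous row permutation leaves the report invariant
  p <- sample(20)
  rep3 <- correlation_report(y[p, ], x[p, ])
  expect_equal(sort(rep3$feature_r), sort(rep2$feature_r), tolerance = 1e-12)

  # constant probe in the truth is excluded with a count
  x2 <- x; x2[, 3] <- 5
  rep4 <- correlation_report(y, x2)
  expect_equal(rep4$n_undefined_features, 1L)
  expect_true(is.na(rep4$feature_r["P3"]))
})

test_that("distribution tests behave on constructed inputs", {
  mk <- function(r) structure(list(feature_r = r), class = "correlation_report")
  set.seed(62)
  base <- rnorm(200)
  # identical distributions: MWU not significant, paired test degenerate-free
  d0 <- distribution_tests(mk(base), mk(base + rnorm(200, 0, 1e-12)))
  expect_gt(d0$mann_whitney$p.value, 0.001)
  # all wins for method 1 -> two-sided binomial p = 2 * 0.5^n
  win <- distribution_tests(mk(base + 1), mk(base))
  expect_equal(win$wins, 200L)
  expect_equal(win$binomial_wins$p.value, min(1, 2 * 0.5^200), tolerance = 1e-12)
  # a 1-SD shift at n = 200 is overwhelmingly significant
  shift <- distribution_tests(mk(base + sd(base)), mk(base))
  expect_lt(shift$mann_whitney$p.value, 1e-6)
  expect_lt(shift$wilcoxon_paired$p.value, 1e-6)
  # variance difference caught by the Levene test
  lev <- distribution_tests(mk(base * 3), mk(base))
  expect_lt(lev$levene$p.value, 1e-4)
})

test_that("bh_adjust reproduces the reference step-up procedure", {
  set.seed(63)
  for (i in 1:100) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
  expect_equal(bh_adjust(c(0.01, NA, 0.5)),
               c(p.adjust(c(0.01, 0.5), "BH")[1], NA, p.adjust(c(0.01, 0.5), "BH")[2]))
})

test_that("mean_variance_summary matches per-column oracles and tracks shrinkage", {
  set.seed(64)
  x <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("P", 1:10)))
  xs <- zscore_apply(x, zscore_fit(x))
  mv <- mean_variance_summary(xs)
  expect_equal(mv$variance, rep(1, 10), tolerance = 1e-12)
  mv_half <- mean_variance_summary(xs * 0.5)
  expect_equal(mv_half$variance, rep(0.25, 10), tolerance = 1e-12)
  expect_equal(mv$mean, unname(colMeans(xs)), tolerance = 1e-14)
  expect_equal(mv$variance, unname(apply(xs, 2, var)), tolerance = 1e-12)
})

test_that("pca_diagnostics projects onto truth PCs with the expected geometry", {
  set.seed(65)
  x <- matrix(rnorm(50 * 12), 50, 12, dimnames = list(NULL, paste0("P", 1:12)))
  d <- pca_diagnostics(x, list(same = x, shrunk = 0.5 * x), k_clusters = 3,
                       n_pcs = 2, seed = 1)
  expect_equal(d$feature$imputed$same, d$feature$truth, tolerance = 1e-10)
  expect_equal(d$sample$imputed$same, d$sample$truth, tolerance = 1e-10)
  # isotropic shrink by s scales projected variance by s^2 (sample-wise, after
  # centering on the truth means the projections contract toward the center)
  v_truth <- apply(d$feature$truth, 2, var)
  v_shrunk <- apply(d$feature$imputed$shrunk, 2, var)
  expect_equal(unname(v_shrunk / v_truth), c(0.25, 0.25), tolerance = 1e-10)
  expect_equal(sort(unique(d$feature$clusters)), 1:3)
})

test_that("phenotype associations recover a planted signal and match hand OLS", {
  set.seed(66)
  n <- 200
  sex <- rbinom(n, 1, 0.5); age <- runif(n, 40, 75)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("P", 1:6)))
  y <- x[, 2] + 0.5 * sex + 0.02 * age + rnorm(n, 0, 0.05)
  ph <- data.frame(trait = y, sex = sex, age = age)
  res <- phenotype_associations(x, ph, c(trait = "continuous"))
  hit <- res[res$probe == "P2", ]
  expect_lt(hit$q, 1e-10)
  expect_equal(hit$effect, 1, tolerance = 0.05)
  expect_true(all(res$q >= res$p - 1e-15))

  # 5-point hand OLS oracle on the residualized phenotype
  x5 <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "P1"))
  ph5 <- data.frame(tr = c(2, 1, 4, 3, 6), sex = c(0, 1, 0, 1, 0),
                    age = c(50, 60, 55, 45, 65))
  r5 <- phenotype_associations(x5, ph5, c(tr = "continuous"))
  yr <- resid(lm(tr ~ sex + age, ph5))
  fit <- lm(yr ~ x5[, 1])
  expect_equal(r5$effect, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(r5$se, summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(r5$p, summary(fit)$coefficients[2, 4], tolerance = 1e-10)

  # binary path: log-odds ratio from logistic regression with covariates
  yb <- rbinom(n, 1, plogis(2 * x[, 3] - 0.2 * sex))
  phb <- data.frame(case = yb, sex = sex, age = age)
  rb <- phenotype_associations(x, phb, c(case = "binary"))
  gl <- glm(yb ~ x[, 3] + sex + age, family = binomial())
  expect_equal(rb$effect[rb$probe == "P3"], unname(coef(gl)[2]), tolerance = 1e-10)
  expect_error(phenotype_associations(x, data.frame(z = rep(1:2, 100), sex = sex,
                                                    age = age),
                                      c(z = "continuous")), "distinct")
})

test_that("permuted phenotypes keep the false-discovery proportion controlled", {
  set.seed(67)
  n <- 120
  fdp <- replicate(100, {
    x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("P", 1:40)))
    ph <- data.frame(y = rnorm(n), sex = rbinom(n, 1, 0.5), age = runif(n, 40, 75))
    res <- phenotype_associations(x, ph, c(y = "continuous"))
    r <- sum(res$significant)
    if (r == 0) 0 else r / r          # all discoveries are false under the null
  })
  # BH guarantees E[FDP] <= 0.05; allow two MC standard errors on the mean
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * se)
})

test_that("association concordance counts recoveries correctly", {
  probes <- paste0("P", 1:10)
  truth <- data.frame(phenotype = "y", probe = probes,
                      effect = seq(0.1, 1, 0.1), se = 0.1,
                      p = c(rep(1e-6, 4), rep(0.5, 6)))
  truth$q <- bh_adjust(truth$p); truth$significant <- truth$q <= 0.05
  same <- truth
  cc <- association_concordance(truth, same)
  expect_equal(cc$mae_significant, 0)
  expect_equal(cc$recovery, 1)
  # constructed half-overlap: 2 of 4 truth hits retained
  half <- truth
  half$significant <- c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6))
  expect_equal(association_concordance(truth, half)$recovery, 0.5)
  # permuted-style results: nothing significant -> recovery 0
  none <- truth; none$significant <- FALSE
  expect_equal(association_concordance(truth, none)$recovery, 0)
})

test_that("stouffer_z matches the closed form", {
  expect_equal(stouffer_z(c(2, 2)), 2 * sqrt(2))
  expect_equal(stouffer_z(c(1.3, -0.4, 2.2)), sum(c(1.3, -0.4, 2.2)) / sqrt(3))
  expect_equal(stouffer_z(cbind(c(1, 2), c(1, 2))), c(sqrt(2), 2 * sqrt(2)))
  expect_equal(stouffer_z(c(3, 1), weights = c(2, 1)), (6 + 1) / sqrt(5))
})

test_that("meta-analysis with an oracle imputer matches native analyses", {
  fx <- fixture_small()
  sb <- fx$data$B
  # oracle: returns the native target rows of the queried samples
  oracle <- function(x) sb[rownames(x), , drop = FALSE]
  expect_error(meta_analysis(fx$data$A, sb, fx$pheno$phenotypes, fx$pheno$types,
                             oracle, fx$data$probe_map, n_replicates = 0),
               "n_replicates")
  meta <- meta_analysis(fx$data$A, sb, fx$pheno$phenotypes, fx$pheno$types,
                        oracle, fx$data$probe_map, n_replicates = 2, seed = 5)
  sm <- meta_summary(meta, min_truth_hits = 5)
  rec <- setNames(sm$recovery, sm$workflow)
  # with perfect imputation the imputed workflows dominate classic
  expect_gte(rec["imputation_separate"], rec["classic"] - 1e-12)
  expect_gte(rec["imputation_combined"], rec["classic"] - 1e-12)
  expect_gt(rec["imputation_combined"], 0.8)
  # replicates are seeded: identical rerun
  meta2 <- meta_analysis(fx$data$A, sb, fx$pheno$phenotypes, fx$pheno$types,
                         oracle, fx$data$probe_map, n_replicates = 2, seed = 5)
  expect_identical(meta$recovery, meta2$recovery)
})
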