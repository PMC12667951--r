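# Attribution on the linear toy has a closed form: for f(x) = x M + c,
# gradient x input with zero baseline gives attr[q, p] = M[q, p] * x_q, so the
# aggregated importance matrix is |M| * colMeans(|x|) row-wise.

toy_setup <- function(seed = 70) {
  model <- linear_toy_model(d_a = 6, d_b = 6, d_z = 4, hidden = 8, seed = seed)
  map <- data.frame(probe_a = model$probes_a, probe_b = model$probes_b)
  set.seed(seed)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, model$probes_a))
  list(model = model, map = map, x = x,
       aff = linear_toy_affine(model, "A2B"))
}

test_that("linear-toy attribution equals |M| scaled by mean absolute input", {
  s <- toy_setup()
  oracle <- abs(s$aff$M) * colMeans(abs(s$x))
  for (method in c("gradient_input", "integrated_gradients")) {
    imp <- importance_matrix(s$model, s$x, "A2B", s$map, method = method)
    expect_lt(max(abs(imp$values - oracle) / (abs(oracle) + 1e-12)), 0.05)
  }
  # expected_gradients agrees in ranking (stochastic baselines shift the scale)
  eg <- importance_matrix(s$model, s$x, "A2B", s$map,
                          method = "expected_gradients", seed = 1)
  expect_gt(cor(as.numeric(eg$values), as.numeric(oracle), method = "spearman"),
            0.8)
  gi <- importance_matrix(s$model, s$x, "A2B", s$map)
  ig <- importance_matrix(s$model, s$x, "A2B", s$map, method = "integrated_gradients")
  expect_gt(cor(as.numeric(gi$values), as.numeric(ig$values),
                method = "spearman"), 0.8)
})

test_that("integrated gradients satisfy completeness on the toy model", {
  s <- toy_setup(71)
  comp <- attribution_completeness(s$model, s$x[1:10, ], "A2B", "B03")
  expect_lt(max(abs(rowSums(comp$attributions) - comp$delta)), 1e-4)
})

test_that("an ignored input receives ~zero attribution", {
  s <- toy_setup(72)
  # zero every first-layer weight from input probe 4: the model ignores it
  s$model$nets$enc_a$layers$lin1$W[4, ] <- 0
  imp <- importance_matrix(s$model, s$x, "A2B", s$map)
  expect_lt(max(imp$values[4, ]), 1e-12)
  expect_gt(max(imp$values[-4, ]), 0)
  expect_error(importance_matrix(s$model, s$x, "A2B", s$map[0, ]), "empty probe_map")
})

test_that("self_cross_split reads the mapped diagonal", {
  s <- toy_setup(73)
  imp <- importance_matrix(s$model, s$x, "A2B", s$map)
  sc <- self_cross_split(imp)
  expect_equal(length(sc$self), 6L)
  expect_equal(unname(sc$self), unname(diag(imp$values)))
  expect_true(all(is.na(diag(sc$cross))))
  expect_equal(sum(!is.na(sc$cross)), 6 * 5)
  # identity-only matrix -> cross all zero
  imp2 <- imp; imp2$values <- diag(0.5, 6); dimnames(imp2$values) <- dimnames(imp$values)
  sc2 <- self_cross_split(imp2)
  expect_true(all(sc2$cross == 0, na.rm = TRUE))
})

test_that("pair_importance takes maxima over orders and directions", {
  s <- toy_setup(74)
  imp_ab <- importance_matrix(s$model, s$x, "A2B", s$map)
  imp_ba <- importance_matrix(s$model,
                              matrix(rnorm(40 * 6), 40, 6,
                                     dimnames = list(NULL, s$model$probes_b)),
                              "B2A", s$map)
  pp <- pair_importance(imp_ab, imp_ba)
  expect_true(isSymmetric(pp))
  v1 <- abs(imp_ab$values); v2 <- abs(imp_ba$values)
  for (i in 2:5) for (j in 1:(i - 1)) {
    expect_equal(pp[i, j], max(v1[i, j], v1[j, i], v2[i, j], v2[j, i]),
                 tolerance = 1e-12)
  }
  # single direction: that direction's max
  p1 <- pair_importance(imp_ab)
  expect_equal(p1[3, 2], max(v1[3, 2], v1[2, 3]), tolerance = 1e-12)
})

test_that("the shared-prefix family rule merges members by maximum", {
  vals <- matrix(c(0, 1, 2,
                   1, 0, 5,
                   2, 5, 0), 3, byrow = TRUE,
                 dimnames = list(c("IL1", "IL2", "TNF1"), c("IL1", "IL2", "TNF1")))
  imp <- structure(list(values = vals, direction = "A2B", method = "gradient_input",
                        probe_map = NULL, aggregation = "", baseline = 0),
                   class = "importance_matrix")
  fam <- pair_importance(imp, family_regex = "[0-9]+$")
  expect_equal(rownames(fam), c("IL", "TNF"))
  expect_equal(fam["IL", "TNF"], 5)   # max over IL1-TNF1 (2) and IL2-TNF1 (5)
})

test_that("pr_curve behaves on separating, random, and hand cases", {
  ids <- paste0("P", 1:20)
  set.seed(75)
  s <- matrix(0, 20, 20, dimnames = list(ids, ids))
  ut <- upper.tri(s)
  # plant 10 reference edges and give them the top scores
  edges_idx <- which(ut, arr.ind = TRUE)[sample(sum(ut), 10), ]
  edges <- reference_edges(data.frame(a = ids[edges_idx[, 1]],
                                      b = ids[edges_idx[, 2]]), ids)
  s[ut] <- runif(sum(ut), 0.001, 0.01)
  for (r in seq_len(10)) s[edges_idx[r, 1], edges_idx[r, 2]] <- 1 + runif(1)
  s <- pmax(s, t(s))
  pr <- pr_curve(s, edges)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_true(all(pr$recall >= 0 & pr$recall <= 1))
  expect_false(is.unsorted(pr$recall[order(-pr$thresholds)]))  # recall grows as thresholds loosen
  expect_gt(pr$auprc, 0.95)

  # random scores: AUPRC near prevalence
  set.seed(76)
  s2 <- matrix(0, 20, 20, dimnames = list(ids, ids))
  s2[ut] <- runif(sum(ut)); s2 <- pmax(s2, t(s2))
  pr2 <- pr_curve(s2, edges)
  expect_lt(abs(pr2$auprc - pr2$prevalence), 0.15)

  # trapezoid hand check: thresholds (2, 1) give PR points (rec 1, prec 1) and
  # (rec 1, prec 0.5); with the recall-0 anchor at precision 1 the area is 1
  expect_equal(xpvae:::.auprc_from_labels(c(2, 1), c(TRUE, FALSE), 2)$auprc, 1,
               tolerance = 1e-12)
  # separating scores across three thresholds: anchored trapezoid by hand
  hand <- xpvae:::.auprc_from_labels(c(4, 2, 1, 0.5), c(TRUE, FALSE, TRUE, FALSE), 3)
  o <- order(c(0, hand$recall))
  pr_pts <- c(hand$precision[1], hand$precision)[o]
  rc_pts <- c(0, hand$recall)[o]
  expect_equal(hand$auprc,
               sum(diff(rc_pts) * (pr_pts[-1] + pr_pts[-length(pr_pts)]) / 2),
               tolerance = 1e-12)

  none <- reference_edges(data.frame(a = "Z1", b = "Z2"), ids)
  expect_error(pr_curve(s, none), "no reference edges")
})

test_that("permutation test implements (k+1)/(n+1) with an exchangeable null", {
  ids <- paste0("P", 1:16)
  set.seed(77)
  s <- matrix(0, 16, 16, dimnames = list(ids, ids))
  ut <- upper.tri(s)
  s[ut] <- runif(sum(ut), 0, 0.01)
  # give the 6 reference edges dominant scores: observed beats every permutation
  pos <- which(ut, arr.ind = TRUE)[1:6, ]
  for (r in 1:6) s[pos[r, 1], pos[r, 2]] <- 10 + r
  s <- pmax(s, t(s))
  edges <- reference_edges(data.frame(a = ids[pos[, 1]], b = ids[pos[, 2]]), ids)
  pt <- permutation_test(s, edges, n = 1000, seed = 1)
  expect_equal(pt$k, 0L)
  expect_equal(pt$p, 1 / 1001)                      # (k+1)/(n+1) with k = 0
  expect_lt(abs(mean(pt$null) - 6 / sum(ut)), 0.1)  # null mean ~ prevalence

  # anti-enriched scores: observed at or below every permutation -> p = 1
  s_bad <- max(s) + 0.01 - s; diag(s_bad) <- NA
  pt2 <- permutation_test(s_bad, edges, n = 200, seed = 2)
  expect_equal(pt2$k, 200L)
  expect_equal(pt2$p, 1)
})

test_that("node importance ranks a globally dominant input first", {
  vals <- matrix(runif(25, 0, 0.1), 5, 5,
                 dimnames = list(paste0("P", 1:5), paste0("P", 1:5)))
  vals[2, ] <- 1                                    # input P2 dominates all outputs
  imp <- structure(list(values = vals, direction = "A2B", method = "gradient_input",
                        probe_map = NULL, aggregation = "", baseline = 0),
                   class = "importance_matrix")
  ni <- node_importance(imp)
  expect_equal(unname(ni$mean_rank["P2"]), 1)
  expect_equal(names(which.min(ni$mean_rank)), "P2")
  # per-column ranking oracle
  oracle <- rowMeans(apply(vals, 2, function(col) rank(-col, ties.method = "average")))
  expect_equal(unname(ni$mean_rank), unname(oracle))
  # ties get average ranks
  tied <- vals; tied[, 1] <- 0.5
  impt <- imp; impt$values <- tied
  expect_equal(unname(node_importance(impt)$mean_rank), unname(rowMeans(
    apply(tied, 2, function(col) rank(-col, ties.method = "average")))))
})

test_that("importance_vs_accuracy recovers constructed relations", {
  set.seed(78)
  ids <- paste0("P", 1:50)
  measured <- setNames(runif(50, 0.2, 0.9), ids)
  self <- measured * 0.05                           # proportional construction
  rep1 <- structure(list(feature_r = setNames(runif(50), ids)),
                    class = "correlation_report")
  res <- importance_vs_accuracy(self, rep1, measured)
  expect_equal(res$r_vs_measured, 1, tolerance = 1e-12)
  indep <- setNames(rnorm(50), ids)
  res2 <- importance_vs_accuracy(setNames(abs(indep), ids), rep1, measured)
  expect_lt(abs(res2$r_vs_measured), 0.45)
  # consistent reordering leaves the summary unchanged
  p <- sample(50)
  res3 <- importance_vs_accuracy(self[p], rep1, measured)
  expect_equal(res3$r_vs_measured, res$r_vs_measured, tolerance = 1e-12)
})
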