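# Loss arithmetic checked against hand evaluations of the printed formulas and
# independent brute-force oracles.

test_that("reconstruction and cross-reconstruction losses match hand formulas", {
  xa <- matrix(c(1, 0), 1); xb <- matrix(c(0, 0), 1)
  expect_equal(reconstruction_loss(xa, xb, xa, xb), 0)
  # N=1, error (1,0) on A, (0,0) on B -> (1/2)(1 + 0) = 0.5
  expect_equal(reconstruction_loss(xa, xb, xa - c(1, 0), xb), 0.5)

  set.seed(10)
  n <- 7
  xa <- matrix(rnorm(n * 4), n); xb <- matrix(rnorm(n * 3), n)
  ha <- matrix(rnorm(n * 4), n); hb <- matrix(rnorm(n * 3), n)
  oracle <- (sum((xa - ha)^2) + sum((xb - hb)^2)) / (2 * n)
  expect_equal(reconstruction_loss(xa, xb, ha, hb), oracle, tolerance = 1e-12)
  expect_equal(cross_reconstruction_loss(xa, xb, ha, hb), oracle, tolerance = 1e-12)
  expect_error(reconstruction_loss(xa, xb, ha[, 1:2], hb))
})

test_that("reconstruction losses are invariant under simultaneous sample permutation", {
  set.seed(11)
  n <- 9
  xa <- matrix(rnorm(n * 5), n); xb <- matrix(rnorm(n * 4), n)
  ha <- matrix(rnorm(n * 5), n); hb <- matrix(rnorm(n * 4), n)
  p <- sample(n)
  expect_equal(reconstruction_loss(xa[p, ], xb[p, ], ha[p, ], hb[p, ]),
               reconstruction_loss(xa, xb, ha, hb), tolerance = 1e-12)
})

.post <- function(mu, lv, platform = "A") {
  structure(list(mu = mu, log_var = lv, platform = platform),
            class = "latent_posterior")
}

test_that("kl_loss is zero at the prior and matches the hand case", {
  z <- matrix(0, 4, 3)
  expect_equal(kl_loss(.post(z, z), .post(z, z, "B")), 0)
  # N=1, d_z=1, mu=1, lv=0 in A only -> L^A = 0.5, total 0.25
  expect_equal(kl_loss(.post(matrix(1), matrix(0)),
                       .post(matrix(0), matrix(0), "B")), 0.25)
})

test_that("kl_loss is non-negative and agrees with a Monte-Carlo estimate", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:5, 1); d <- sample(1:4, 1)
    mu <- matrix(rnorm(n * d), n); lv <- matrix(rnorm(n * d, 0, 0.7), n)
    got <- kl_loss(.post(mu, lv), .post(mu, lv, "B"))   # both posteriors equal
    expect_gte(got, 0)
    # MC estimate of E_q[log q - log p] per sample, averaged, for one platform
    m <- 1e5
    kl_mc <- mean(vapply(seq_len(n), function(s) {
      sd_s <- exp(0.5 * lv[s, ])
      z <- matrix(rnorm(m * d), m, d) %*% diag(sd_s, d) +
        matrix(mu[s, ], m, d, byrow = TRUE)
      lq <- rowSums(dnorm(z, matrix(mu[s, ], m, d, byrow = TRUE),
                          matrix(sd_s, m, d, byrow = TRUE), log = TRUE))
      lp <- rowSums(dnorm(z, 0, 1, log = TRUE))
      mean(lq - lp)
    }, numeric(1)))
    # the printed bracket is twice the per-dimension KL, cancelled by the outer
    # 1/2N: each platform term equals the mean per-sample KL, and with both
    # posteriors equal kl_loss is exactly that mean
    se <- 0.02 * max(1, abs(kl_mc))   # generous MC tolerance at m = 1e5
    expect_equal(got, kl_mc, tolerance = max(3 * se, 0.02))
  }
})

test_that("rbf_kernel follows the printed form and is symmetric", {
  u <- c(1, 2, 3)
  expect_equal(rbf_kernel(u, u, 2), 1)
  # ||u - v|| = gamma * sqrt(2) -> exp(-1)
  g <- 1.7
  v <- u + c(g * sqrt(2), 0, 0)
  expect_equal(rbf_kernel(u, v, g), exp(-1), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4); g <- runif(1, 0.5, 3)
    expect_equal(rbf_kernel(a, b, g), rbf_kernel(b, a, g), tolerance = 1e-15)
    expect_equal(rbf_kernel(a, b, g), exp(-sum((a - b)^2) / (2 * g^2)),
                 tolerance = 1e-14)
  }
})

test_that("median_heuristic matches a double-loop oracle and floors degenerate input", {
  za <- matrix(c(0, 0), 1); zb <- matrix(c(3, 4), 1)
  expect_equal(median_heuristic(za, zb), 5)            # two points at distance 5
  expect_warning(g <- median_heuristic(za, za), "coincident")
  expect_gt(g, 0)
  set.seed(14)
  za <- matrix(rnorm(12), 6); zb <- matrix(rnorm(12), 6)
  pool <- rbind(za, zb)
  dd <- c()
  for (i in 1:11) for (j in (i + 1):12) dd <- c(dd, sqrt(sum((pool[i, ] - pool[j, ])^2)))
  expect_equal(median_heuristic(za, zb), median(dd), tolerance = 1e-12)
})

mmd_oracle <- function(za, zb, gamma) {
  n <- nrow(za)
  s_within <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) {
    s_within <- s_within + rbf_kernel(za[i, ], za[j, ], gamma) +
      rbf_kernel(zb[i, ], zb[j, ], gamma)
  }
  s_cross <- 0
  for (i in 1:n) for (j in 1:n) s_cross <- s_cross + rbf_kernel(za[i, ], zb[j, ], gamma)
  s_within / (n * (n - 1)) - 2 * s_cross / n^2
}

test_that("mmd_loss equals the printed U-statistic on hand cases", {
  a <- c(0.3, -0.2)
  za <- rbind(a, a)
  expect_equal(mmd_loss(za, za, gamma = 1), 0, tolerance = 1e-14)  # coincident
  b <- c(1.1, 0.4)
  z2 <- rbind(a, b)
  g <- 0.8
  expect_equal(mmd_loss(z2, z2, gamma = g), rbf_kernel(a, b, g) - 1,
               tolerance = 1e-12)                                   # k(a,b) - 1 <= 0
  expect_lte(mmd_loss(z2, z2, gamma = g), 0)
  expect_error(mmd_loss(za[1, , drop = FALSE], za[1, , drop = FALSE]), ">= 2")
})

test_that("mmd_loss sign behavior: ~0 for same distribution, positive for separated clouds", {
  set.seed(15)
  vals <- replicate(40, {
    za <- matrix(rnorm(32 * 3), 32)
    zb <- matrix(rnorm(32 * 3), 32)
    mmd_loss(za, zb)
  })
  expect_lt(abs(mean(vals)), 0.02)     # unbiased: expectation ~ 0
  za <- matrix(rnorm(32 * 3), 32)
  zb <- matrix(rnorm(32 * 3), 32) + 10 # separation >> gamma
  expect_gt(mmd_loss(za, zb), 0.5)
})

test_that("total_loss combines components with the trained default weights", {
  lb <- total_loss(1, 1, 1, 1)
  expect_equal(lb$total, 0.90 + 1.4 + 1.4e-4 + 1.9)
  expect_equal(total_loss(3, 5, 7, 11, loss_weights(0, 0, 0, 0))$total, 0)
  set.seed(16)
  for (i in 1:10) {
    comp <- runif(4, -1, 3); w <- runif(4, 0, 2)
    lw <- loss_weights(w[1], w[2], w[3], w[4])
    expect_equal(total_loss(comp[1], comp[2], comp[3], comp[4], lw)$total,
                 sum(w * comp), tolerance = 1e-12)   # dot-product oracle
  }
  expect_error(loss_weights(-0.1), "non-negative")
})

test_that("jvae_forward composes exactly the standalone loss operations", {
  set.seed(17)
  model <- linear_toy_model(d_a = 6, d_b = 5, d_z = 3, seed = 5)
  model$kernel <- kernel_config("fixed", gamma = 1.2)
  n <- 8
  xa <- matrix(rnorm(n * 6), n); xb <- matrix(rnorm(n * 5), n)
  ea <- matrix(rnorm(n * 3), n); eb <- matrix(rnorm(n * 3), n)
  fw <- jvae_forward(model, xa, xb, ea, eb)
  expect_equal(fw$loss$rec,
               reconstruction_loss(xa, xb, fw$xhat_a, fw$xhat_b), tolerance = 1e-12)
  expect_equal(fw$loss$cross,
               cross_reconstruction_loss(xa, xb, fw$xtilde_a, fw$xtilde_b),
               tolerance = 1e-12)
  expect_equal(fw$loss$kl, kl_loss(fw$post_a, fw$post_b), tolerance = 1e-12)
  expect_equal(fw$loss$align, mmd_loss(fw$z_a, fw$z_b, gamma = 1.2), tolerance = 1e-12)
  expect_equal(fw$loss$total,
               total_loss(fw$loss$rec, fw$loss$cross, fw$loss$kl, fw$loss$align,
                          model$weights)$total, tolerance = 1e-12)
  # reparameterization consistency on the same draws
  expect_equal(fw$z_a, reparameterize(fw$post_a, ea), tolerance = 1e-12)
  # eps = 0 path is deterministic
  z0 <- matrix(0, n, 3)
  f1 <- jvae_forward(model, xa, xb, z0, z0)
  f2 <- jvae_forward(model, xa, xb, z0, z0)
  expect_identical(f1$loss$total, f2$loss$total)
})

test_that("mmd_loss matches the double-loop oracle on random instances", {
  set.seed(18)
  for (i in 1:10) {
    n <- sample(2:16, 1); d <- sample(1:6, 1)
    za <- matrix(rnorm(n * d), n); zb <- matrix(rnorm(n * d), n)
    g <- runif(1, 0.3, 2.5)
    expect_equal(mmd_loss(za, zb, gamma = g), mmd_oracle(za, zb, g),
                 tolerance = 1e-10)
  }
})
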