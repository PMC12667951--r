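#' Generate a paired-platform synthetic cohort with known ground truth
#'
#' Emulates the statistical structure cross-platform imputation assumes: K
#' shared standard-normal latent factors drive both platforms through sparse
#' loadings (`X = g(Z W) + noise`), with tunable per-feature cross-platform
#' concordance via the noise level, a stated fraction of discordant probes
#' (whose A- and B-side loadings use disjoint factors), and planted dependency
#' edges between mapped probes sharing a dominant factor. Matrices are
#' returned unstandardized and positive-shifted so the log2 path is
#' exercisable; shifting does not change correlations.
#'
#' Probe i of platform A (`A001`, ...) corresponds one-to-one to probe i of
#' platform B (`B001`, ...) for `i <= min(d_a, d_b)`. Each probe loads on its
#' dominant factor (magnitude U(0.8, 1.2), random sign) plus up to two minor
#' factors (U(0.2, 0.5)); dominant factors are assigned round-robin so every
#' factor supports at least two probes and planted edges are well defined.
#'
#' @param n Samples.
#' @param d_a,d_b Probes per platform.
#' @param k Latent factors (k <= min(d_a, d_b)).
#' @param noise_level Baseline per-probe noise SD; each probe's SD is drawn
#'   U(0.5, 1.5) times this. Default 0.5 (moderate noise: signal fraction
#'   about 0.8 for unit loadings).
#' @param frac_discordant Fraction of mapped probes made discordant.
#' @param nonlinear Apply a mild tanh saturation `g(u) = 0.7 u + 0.6 tanh(u/2)`
#'   emulating assay dynamic-range compression.
#' @param seed Integer seed; the cohort is a pure function of the arguments.
#' @return List with `data` (a `paired_platforms` with probe map) and `truth`
#'   (a `synthetic_truth`: Z, loadings, noise SDs, planted `edges`,
#'   `discordant` probe IDs, shifts, seed).
#' @export
generate_cohort <- function(n, d_a, d_b, k, noise_level = 0.5,
                            frac_discordant = 0.1, nonlinear = FALSE, seed = 1L) {
  stopifnot(n >= 2, d_a >= 1, d_b >= 1, k >= 1)
  if (k > min(d_a, d_b)) stop("k must be <= min(d_a, d_b)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- min(d_a, d_b)
  probes_a <- sprintf("A%03d", seq_len(d_a))
  probes_b <- sprintf("B%03d", seq_len(d_b))

  dominant <- ((seq_len(max(d_a, d_b)) - 1L) %% k) + 1L   # round-robin
  draw_loadings <- function(d, dom, disc_shift = 0L) {
    w <- matrix(0, k, d)
    for (j in seq_len(d)) {
      f <- ((dom[j] - 1L + disc_shift) %% k) + 1L
      w[f, j] <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.8, 1.2)
      extra <- sample(0:2, 1L)
      if (extra > 0L && k > 1L) {
        others <- sample(setdiff(seq_len(k), f), min(extra, k - 1L))
        w[others, j] <- sample(c(-1, 1), length(others), replace = TRUE) *
          stats::runif(length(others), 0.2, 0.5)
      }
    }
    w
  }
  w_a <- draw_loadings(d_a, dominant[seq_len(d_a)])
  w_b <- matrix(0, k, d_b)
  # concordant mapped probes share A's support with jittered magnitudes
  for (j in seq_len(m)) {
    w_b[, j] <- w_a[, j] * stats::runif(k, 0.7, 1.3)
  }
  if (d_b > m) w_b[, (m + 1L):d_b] <- draw_loadings(d_b - m, dominant[(m + 1L):d_b])

  n_disc <- floor(frac_discordant * m)
  discordant_idx <- if (n_disc > 0L) sort(sample.int(m, n_disc)) else integer(0)
  for (j in discordant_idx) {
    # B side re-drawn on factors disjoint from the A side's support
    support_a <- which(w_a[, j] != 0)
    free <- setdiff(seq_len(k), support_a)
    if (length(free) == 0L) next
    w_b[, j] <- 0
    f <- free[1L + (j %% length(free))]
    w_b[f, j] <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.8, 1.2)
  }

  sigma_a <- stats::runif(d_a, 0.5, 1.5) * noise_level
  sigma_b <- stats::runif(d_b, 0.5, 1.5) * noise_level
  z <- matrix(stats::rnorm(n * k), n, k)
  g <- if (nonlinear) function(u) 0.7 * u + 0.6 * tanh(u / 2) else identity
  x_a <- g(z %*% w_a) + matrix(stats::rnorm(n * d_a), n, d_a) %*% diag(sigma_a, d_a)
  x_b <- g(z %*% w_b) + matrix(stats::rnorm(n * d_b), n, d_b) %*% diag(sigma_b, d_b)
  shift_a <- 0.5 - min(x_a); shift_b <- 0.5 - min(x_b)
  x_a <- x_a + shift_a; x_b <- x_b + shift_b
  samples <- sprintf("S%05d", seq_len(n))
  dimnames(x_a) <- list(samples, probes_a)
  dimnames(x_b) <- list(samples, probes_b)

  # planted edges: unordered pairs of concordant mapped probes sharing a
  # dominant factor
  conc <- setdiff(seq_len(m), discordant_idx)
  dom_m <- dominant[seq_len(m)]
  edges <- do.call(rbind, lapply(seq_len(k), function(f) {
    members <- conc[dom_m[conc] == f]
    if (length(members) < 2L) return(NULL)
    t(utils::combn(probes_a[members], 2L))
  }))
  edges <- if (is.null(edges)) {
    data.frame(probe1 = character(0), probe2 = character(0))
  } else {
    data.frame(probe1 = edges[, 1L], probe2 = edges[, 2L], stringsAsFactors = FALSE)
  }

  probe_map <- data.frame(probe_a = probes_a[seq_len(m)],
                          probe_b = probes_b[seq_len(m)],
                          stringsAsFactors = FALSE)
  data <- paired_platforms(x_a, x_b, probe_map = probe_map)
  truth <- structure(list(z = z, w_a = w_a, w_b = w_b,
                          sigma_a = stats::setNames(sigma_a, probes_a),
                          sigma_b = stats::setNames(sigma_b, probes_b),
                          dominant = stats::setNames(dominant[seq_len(max(d_a, d_b))], NULL),
                          edges = edges,
                          discordant = probes_a[discordant_idx],
                          nonlinear = nonlinear,
                          shift_a = shift_a, shift_b = shift_b,
                          noise_level = noise_level, seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(data = data, truth = truth)
}

#' Preset synthetic cohorts
#'
#' `small`: N = 600, 60 probes per platform, 10 factors. `medium`: N = 3000,
#' 300 probes, 30 factors.
#'
#' @param preset `"small"` or `"medium"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generate_cohort()].
#' @return As [generate_cohort()].
#' @export
generate_preset <- function(preset = c("small", "medium"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
                 small = list(n = 600L, d_a = 60L, d_b = 60L, k = 10L),
                 medium = list(n = 3000L, d_a = 300L, d_b = 300L, k = 30L))
  over <- list(...)
  args[names(over)] <- over
  do.call(generate_cohort, c(args, list(seed = seed)))
}

#' Closed-form expected cross-platform correlation of a mapped probe
#'
#' For the linear generator, probe j's measured cross-platform Pearson r is
#' `r = (w_A . w_B) / sqrt((||w_A||^2 + sigma_A^2) (||w_B||^2 + sigma_B^2))`.
#'
#' @param truth A `synthetic_truth` (linear; errors on nonlinear cohorts).
#' @param probe Mapped probe index or platform-A probe ID.
#' @return Expected Pearson r.
#' @export
expected_feature_r <- function(truth, probe) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$nonlinear) stop("closed form holds for the linear generator only")
  j <- if (is.character(probe)) match(probe, names(truth$sigma_a)) else probe
  if (is.na(j) || j > ncol(truth$w_b)) stop("unknown mapped probe: ", probe)
  wa <- truth$w_a[, j]; wb <- truth$w_b[, j]
  unname(sum(wa * wb) / sqrt((sum(wa^2) + truth$sigma_a[j]^2) *
                               (sum(wb^2) + truth$sigma_b[j]^2)))
}

#' Generate latent-factor-driven phenotypes with sex/age covariates
#'
#' Continuous phenotypes: `y = Z c * effect + 0.5 sex + 0.02 age + noise` with
#' each phenotype driven by 1-3 factors; binary phenotypes pass the centered
#' linear predictor through a logistic link. `sex ~ Bernoulli(0.5)`,
#' `age ~ U(40, 75)`. Truth-associated probes (those loading on a phenotype's
#' driving factors) are recorded per phenotype.
#'
#' @param truth A `synthetic_truth`.
#' @param n_continuous,n_binary Phenotype counts.
#' @param effect_size Scale of the factor coefficients (0 = no associations).
#' @param noise_sd Residual SD of continuous phenotypes.
#' @param seed Integer seed (independent of the cohort's).
#' @return List: `phenotypes` (data.frame with phenotype columns plus `sex`,
#'   `age`), `types` (named vector), `truth_probes` (named list of
#'   platform-A/B probe-index vectors per phenotype), `coefficients` (K x
#'   n_pheno matrix).
#' @export
generate_phenotypes <- function(truth, n_continuous = 3L, n_binary = 3L,
                                effect_size = 1, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  z <- truth$z
  n <- nrow(z); k <- ncol(z)
  n_ph <- n_continuous + n_binary
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 40, 75)
  coefs <- matrix(0, k, n_ph)
  ph <- data.frame(row.names = seq_len(n))
  types <- character(0)
  truth_probes <- list()
  probes_a <- names(truth$sigma_a)
  for (p in seq_len(n_ph)) {
    nm <- if (p <= n_continuous) sprintf("cont%02d", p)
          else sprintf("bin%02d", p - n_continuous)
    drivers <- sample.int(k, sample(1:3, 1L))
    if (effect_size != 0) {
      coefs[drivers, p] <- sample(c(-1, 1), length(drivers), replace = TRUE) *
        stats::runif(length(drivers), 0.8, 1.2) * effect_size
    }
    lin <- as.numeric(z %*% coefs[, p]) + 0.5 * sex + 0.02 * age
    if (p <= n_continuous) {
      ph[[nm]] <- lin + stats::rnorm(n, 0, noise_sd)
      types[nm] <- "continuous"
    } else {
      pr <- stats::plogis(lin - mean(lin))
      ph[[nm]] <- stats::rbinom(n, 1L, pr)
      types[nm] <- "binary"
    }
    assoc <- if (effect_size == 0) integer(0) else
      which(colSums(abs(truth$w_a[drivers, , drop = FALSE])) > 0)
    truth_probes[[nm]] <- probes_a[assoc]
  }
  ph$sex <- sex
  ph$age <- age
  list(phenotypes = ph, types = types, truth_probes = truth_probes,
       coefficients = coefs)
}

#' Generate a second cohort from the same ground truth
#'
#' New latent draws through the same loadings and noise model, with per-probe
#' location (and optional scale) shifts emulating an external cohort measured
#' under different conditions.
#'
#' @param truth A `synthetic_truth`.
#' @param n2 Samples in the second cohort.
#' @param mean_shift Scalar or per-probe vector added to every probe (applied
#'   to both platforms).
#' @param scale Multiplicative per-probe scale change (default 1).
#' @param seed Integer seed (independent of cohort 1's).
#' @return List with `data` (a `paired_platforms`) and `z` (the new factors).
#' @export
generate_second_cohort <- function(truth, n2, mean_shift = 0, scale = 1,
                                   seed = 2L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  k <- nrow(truth$w_a)
  d_a <- ncol(truth$w_a); d_b <- ncol(truth$w_b)
  z <- matrix(stats::rnorm(n2 * k), n2, k)
  g <- if (truth$nonlinear) function(u) 0.7 * u + 0.6 * tanh(u / 2) else identity
  x_a <- g(z %*% truth$w_a) +
    matrix(stats::rnorm(n2 * d_a), n2, d_a) %*% diag(truth$sigma_a, d_a)
  x_b <- g(z %*% truth$w_b) +
    matrix(stats::rnorm(n2 * d_b), n2, d_b) %*% diag(truth$sigma_b, d_b)
  x_a <- sweep(x_a * if (length(scale) == 1L) scale else rep(scale, length.out = d_a),
               2L, rep(mean_shift, length.out = d_a) + truth$shift_a, "+")
  x_b <- sweep(x_b * if (length(scale) == 1L) scale else rep(scale, length.out = d_b),
               2L, rep(mean_shift, length.out = d_b) + truth$shift_b, "+")
  samples <- sprintf("T%05d", seq_len(n2))
  dimnames(x_a) <- list(samples, names(truth$sigma_a))
  dimnames(x_b) <- list(samples, names(truth$sigma_b))
  m <- min(d_a, d_b)
  probe_map <- data.frame(probe_a = names(truth$sigma_a)[seq_len(m)],
                          probe_b = names(truth$sigma_b)[seq_len(m)],
                          stringsAsFactors = FALSE)
  list(data = paired_platforms(x_a, x_b, probe_map = probe_map), z = z)
}
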