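.parse_direction <- function(direction) {
  d <- toupper(gsub("[^A-B2]", "", direction))
  if (d %in% c("A2B", "AB")) list(src = "A", tgt = "B")
  else if (d %in% c("B2A", "BA")) list(src = "B", tgt = "A")
  else stop("direction must be 'A2B' or 'B2A'")
}

#' Impute the other platform's profile
#'
#' Encodes standardized source-platform profiles and decodes them with the
#' target platform's decoder. The default point estimate decodes the posterior
#' mean (deterministic); `mode = "sample"` decodes one reparameterized draw
#' for uncertainty exploration.
#'
#' @param model A trained `jvae`.
#' @param x_source Standardized matrix, samples x source width. Columns must
#'   match the model's source width (and probe universe when recorded).
#' @param direction `"A2B"` or `"B2A"`.
#' @param mode `"mean"` (default) or `"sample"`.
#' @param seed Seed for the reparameterized draw when `mode = "sample"`.
#' @return Imputed matrix, samples x target width, on the standardized scale.
#' @export
impute <- function(model, x_source, direction, mode = c("mean", "sample"),
                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "jvae"), is.matrix(x_source))
  dir <- .parse_direction(direction)
  d_src <- if (dir$src == "A") model$config$d_a else model$config$d_b
  if (ncol(x_source) != d_src) {
    stop(sprintf("source width %d does not match model width %d",
                 ncol(x_source), d_src))
  }
  src_probes <- if (dir$src == "A") model$probes_a else model$probes_b
  if (!is.null(src_probes) && !is.null(colnames(x_source))) {
    if (!identical(colnames(x_source), src_probes)) {
      if (!all(src_probes %in% colnames(x_source))) {
        stop("input probes do not cover the model's source probe universe")
      }
      x_source <- x_source[, src_probes, drop = FALSE]
    }
  }
  cm <- colMeans(x_source)
  if (stats::median(abs(cm)) > 0.5) {
    warning("input columns look unstandardized (median |column mean| > 0.5); ",
            "impute expects feature-wise Z-scored inputs")
  }
  post <- encode(model, x_source, dir$src, training = FALSE)
  z <- if (mode == "mean") post$mu else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    reparameterize(post, matrix(stats::rnorm(length(post$mu)),
                                nrow(post$mu), ncol(post$mu)))
  }
  out <- decode(model, z, dir$tgt, training = FALSE)
  rownames(out) <- rownames(x_source)
  tgt_probes <- if (dir$tgt == "A") model$probes_a else model$probes_b
  if (!is.null(tgt_probes)) colnames(out) <- tgt_probes
  out
}

#' Posterior-mean latent embedding of a batch
#'
#' @param model A `jvae`.
#' @param x Standardized batch.
#' @param platform `"A"` or `"B"`.
#' @return Samples x d_z matrix of posterior means.
#' @export
latent_embed <- function(model, x, platform) {
  out <- encode(model, x, platform, training = FALSE)$mu
  rownames(out) <- rownames(x)
  out
}

#' Apply a trained model to an external cohort
#'
#' External cohorts are standardized with parameters fit on their own
#' distribution (never with training-cohort parameters), must supply every
#' model input probe (no silent zero-filling), and may restrict the output to
#' a subset of target probes. Optionally de-standardizes the imputed values
#' into a target cohort's units.
#'
#' @param model A trained `jvae` with recorded probe universes.
#' @param external Unstandardized matrix (samples x probes) with probe
#'   colnames; extra probes are ignored.
#' @param direction `"A2B"` or `"B2A"` (source = the external platform).
#' @param target_probes Optional subset of target probe IDs to keep.
#' @param target_params Optional `standardization_params` of a target cohort;
#'   when given the output is de-standardized into those units.
#' @param cohort Name tag for the external cohort (provenance of the fitted
#'   standardization).
#' @return List: `imputed` (matrix), `standardization` (the external cohort's
#'   own fitted parameters).
#' @export
apply_external <- function(model, external, direction, target_probes = NULL,
                           target_params = NULL, cohort = "external") {
  stopifnot(inherits(model, "jvae"), is.matrix(external),
            !is.null(colnames(external)))
  dir <- .parse_direction(direction)
  src_probes <- if (dir$src == "A") model$probes_a else model$probes_b
  if (is.null(src_probes)) stop("model carries no probe universe; cannot match external probes")
  missing <- setdiff(src_probes, colnames(external))
  if (length(missing) > 0L) {
    stop("external cohort is missing model input probes: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" ... (%d total)", length(missing)) else "")
  }
  x <- external[, src_probes, drop = FALSE]
  params <- zscore_fit(x, cohort = cohort)   # always the cohort's own distribution
  xs <- zscore_apply(x, params, cohort = cohort)
  imp <- impute(model, xs, direction)
  if (!is.null(target_probes)) {
    unknown <- setdiff(target_probes, colnames(imp))
    if (length(unknown) > 0L) stop("requested target probes absent from model output: ",
                                   paste(unknown, collapse = ", "))
    imp <- imp[, target_probes, drop = FALSE]
  }
  if (!is.null(target_params)) {
    keep <- intersect(colnames(imp), target_params$probes)
    sub <- target_params
    sub$mean <- sub$mean[keep]; sub$sd <- sub$sd[keep]; sub$probes <- keep
    imp <- zscore_invert(imp[, keep, drop = FALSE], sub)
  }
  list(imputed = imp, standardization = params)
}
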