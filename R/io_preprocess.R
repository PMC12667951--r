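#' Read one platform's measurement matrix from delimited text
#'
#' Reads a TSV/CSV table whose header row holds probe IDs and whose first
#' column holds sample IDs (the layout Olink NPX and SomaScan RFU exports are
#' commonly reshaped into). Values must be numeric; empty cells and `NA` are
#' kept as missing, never silently zero-filled.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `"auto"` lets [data.table::fread()] sniff it.
#' @param samples_in_rows If `FALSE` the file is transposed on read, i.e. the
#'   file has probes in rows and samples in columns.
#' @return A numeric matrix (samples x probes) with sample IDs as rownames and
#'   probe IDs as colnames, in file order.
#' @export
read_matrix <- function(path, sep = "auto", samples_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = if (identical(sep, "auto")) "auto" else sep,
                          header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("matrix file needs an ID column plus at least one data column: ", path)
  ids <- as.character(dt[[1L]])
  probes <- colnames(dt)[-1L]
  if (anyDuplicated(probes)) {
    stop("duplicated probe IDs in header of ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sample IDs in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- as.matrix(dt[, -1L, drop = FALSE])
  if (is.character(x)) {
    num <- suppressWarnings(matrix(as.numeric(x), nrow = nrow(x)))
    bad <- which(is.na(num) & !is.na(x) & nzchar(trimws(x)) & toupper(trimws(x)) != "NA",
                 arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s: '%s'",
                   ids[bad[1L, 1L]], probes[bad[1L, 2L]], path, x[bad[1L, , drop = FALSE]]))
    }
    x <- num
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(ids, probes)
  if (!samples_in_rows) {
    x <- t(x)
  }
  x
}

#' Write a platform matrix as delimited text
#'
#' Inverse of [read_matrix()]: first column `sample_id`, one column per probe.
#'
#' @param x Numeric matrix with sample rownames and probe colnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_matrix <- function(x, path, sep = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Elementwise log2 transform of a positive measurement matrix
#'
#' Applied to SomaScan RFU values before standardization; Olink NPX is already
#' on a log2 scale and must not be transformed again.
#'
#' @param x Numeric matrix with strictly positive entries.
#' @return `log2(x)`.
#' @export
log2_transform <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  nonpos <- colSums(x <= 0, na.rm = TRUE) > 0
  if (any(nonpos)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
    stop("log2_transform: non-positive values in probes: ",
         paste(nm[nonpos], collapse = ", "))
  }
  log2(x)
}

#' Fit, apply, and invert feature-wise Z-score standardization
#'
#' Each probe is scaled to mean 0 and standard deviation 1 (sample SD,
#' denominator n-1). Parameters carry a cohort tag so that the pipeline can
#' refuse to apply one cohort's parameters to another cohort: external cohorts
#' are always standardized with parameters fit on their own distribution.
#'
#' @param x Numeric matrix, samples x probes, probe colnames required.
#' @param cohort Character tag recording which cohort the parameters describe.
#' @return An object of class `standardization_params` with fields `mean`,
#'   `sd`, `probes`, `cohort`.
#' @export
zscore_fit <- function(x, cohort = "unnamed") {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (nrow(x) < 2L) stop("zscore_fit needs at least 2 samples")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  bad <- !is.finite(sd) | sd <= 0
  if (any(bad)) {
    stop("zscore_fit: zero-variance probes (drop them first): ",
         paste(colnames(x)[bad], collapse = ", "))
  }
  structure(list(mean = mu, sd = sd, probes = colnames(x), cohort = cohort),
            class = "standardization_params")
}

#' @rdname zscore_fit
#' @param params A `standardization_params` object.
#' @param cohort Optional tag of the cohort `x` belongs to; if it differs from
#'   `params$cohort` the call errors unless `allow_foreign = TRUE`.
#' @param allow_foreign Explicit override of the own-cohort rule.
#' @export
zscore_apply <- function(x, params, cohort = NULL, allow_foreign = FALSE) {
  stopifnot(inherits(params, "standardization_params"), is.matrix(x))
  if (!is.null(cohort) && !identical(cohort, params$cohort) && !allow_foreign) {
    stop(sprintf(paste0("standardization parameters were fit on cohort '%s' but data ",
                        "are from cohort '%s'; fit parameters on the cohort's own ",
                        "distribution or set allow_foreign = TRUE"),
                 params$cohort, cohort))
  }
  x <- x[, params$probes, drop = FALSE]
  sweep(sweep(x, 2L, params$mean, "-"), 2L, params$sd, "/")
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(x, params) {
  stopifnot(inherits(params, "standardization_params"), is.matrix(x))
  x <- x[, params$probes, drop = FALSE]
  sweep(sweep(x, 2L, params$sd, "*"), 2L, params$mean, "+")
}

#' Serialize / restore standardization parameters as JSON
#' @param params A `standardization_params` object.
#' @param path JSON file path.
#' @export
write_standardization <- function(params, path) {
  stopifnot(inherits(params, "standardization_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$mean <- stats::setNames(as.numeric(p$mean), p$probes)
  p$sd <- stats::setNames(as.numeric(p$sd), p$probes)
  structure(p, class = "standardization_params")
}

#' Four-way sample split (train / early-stop / tune / test)
#'
#' Partitions `1:n` into four disjoint, exhaustive index sets. The default
#' fractions follow the 60/10/10/20 design: training, early stopping (guards
#' model parameters against overfitting), hyperparameter tuning, and held-out
#' test. Sizes are floors of the fractions; leftover samples are handed to the
#' sets in declared order, so no sample is lost or duplicated.
#'
#' @param n Number of samples (>= 4 unless some fractions are zero).
#' @param fractions Four non-negative numbers summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `split_assignment`: list with integer vectors
#'   `train`, `early_stop`, `tune`, `test` plus `seed` and `fractions`.
#' @export
make_splits <- function(n, fractions = c(0.6, 0.1, 0.1, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 4L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n < sum(fractions > 0)) stop("n too small for the requested fractions")
  sizes <- floor(fractions * n)
  left <- n - sum(sizes)
  i <- 1L
  while (left > 0L) {           # remainders to sets in declared order
    if (fractions[i] > 0) { sizes[i] <- sizes[i] + 1L; left <- left - 1L }
    i <- if (i == 4L) 1L else i + 1L
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  sets <- lapply(seq_len(4L), function(j) {
    if (sizes[j] == 0L) integer(0) else sort(perm[starts[j]:ends[j]])
  })
  structure(list(train = sets[[1L]], early_stop = sets[[2L]], tune = sets[[3L]],
                 test = sets[[4L]], seed = as.integer(seed), fractions = fractions),
            class = "split_assignment")
}

#' @rdname make_splits
#' @param split A `split_assignment`.
#' @param path JSON path.
#' @export
write_splits <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_splits
#' @export
read_splits <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train", "early_stop", "tune", "test")) s[[f]] <- as.integer(s[[f]])
  structure(s, class = "split_assignment")
}

#' Pair two platform halves on their shared samples
#'
#' Keeps the intersection of sample IDs, in the order of platform A, reorders
#' platform B's rows to match, and reports dropped IDs.
#'
#' @param half_a,half_b Numeric matrices with sample rownames (from
#'   [read_matrix()]).
#' @param probe_map Optional probe correspondence (see [match_probes()]).
#' @return An object of class `paired_platforms`: list with `samples`, `A`,
#'   `B`, `probes_a`, `probes_b`, `probe_map`, `dropped_a`, `dropped_b`.
#' @export
align_samples <- function(half_a, half_b, probe_map = NULL) {
  stopifnot(is.matrix(half_a), is.matrix(half_b),
            !is.null(rownames(half_a)), !is.null(rownames(half_b)))
  shared <- intersect(rownames(half_a), rownames(half_b))
  if (length(shared) == 0L) stop("no shared sample IDs between platforms")
  dropped_a <- setdiff(rownames(half_a), shared)
  dropped_b <- setdiff(rownames(half_b), shared)
  if (length(dropped_a) || length(dropped_b)) {
    message(sprintf("align_samples: dropped %d sample(s) unique to A, %d unique to B",
                    length(dropped_a), length(dropped_b)))
  }
  paired_platforms(half_a[shared, , drop = FALSE], half_b[shared, , drop = FALSE],
                   probe_map = probe_map, dropped_a = dropped_a, dropped_b = dropped_b)
}

#' Construct a paired-platform container
#'
#' The central data structure: two sample-aligned real matrices plus probe
#' metadata and an optional one-to-one probe correspondence.
#'
#' @param A,B Numeric matrices with identical rownames (samples) and unique
#'   probe colnames.
#' @param probe_map Optional two-column data.frame (`probe_a`, `probe_b`).
#' @param dropped_a,dropped_b Sample IDs removed during alignment (metadata).
#' @return `paired_platforms` object.
#' @export
paired_platforms <- function(A, B, probe_map = NULL,
                             dropped_a = character(0), dropped_b = character(0)) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == nrow(B),
            identical(rownames(A), rownames(B)))
  if (anyDuplicated(colnames(A)) || anyDuplicated(colnames(B))) {
    stop("probe IDs must be unique within a platform")
  }
  if (!is.null(probe_map)) {
    probe_map <- .validate_probe_map(probe_map, colnames(A), colnames(B))
  }
  structure(list(samples = rownames(A), A = A, B = B,
                 probes_a = colnames(A), probes_b = colnames(B),
                 probe_map = probe_map,
                 dropped_a = dropped_a, dropped_b = dropped_b),
            class = "paired_platforms")
}

.validate_probe_map <- function(map, probes_a, probes_b) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  colnames(map)[1:2] <- c("probe_a", "probe_b")
  if (!all(map$probe_a %in% probes_a) || !all(map$probe_b %in% probes_b)) {
    stop("probe_map references probes absent from the platforms")
  }
  if (anyDuplicated(map$probe_a) || anyDuplicated(map$probe_b)) {
    stop("probe_map must be one-to-one: a probe appears more than once")
  }
  map[, c("probe_a", "probe_b")]
}

#' @export
print.paired_platforms <- function(x, ...) {
  cat(sprintf("paired_platforms: %d samples; platform A %d probes, platform B %d probes; %s mapped pairs\n",
              length(x$samples), length(x$probes_a), length(x$probes_b),
              if (is.null(x$probe_map)) "no" else nrow(x$probe_map)))
  invisible(x)
}

#' One-to-one probe matching from a correspondence table
#'
#' Keeps only rows whose probes exist on both platforms and where each probe
#' occurs exactly once among the surviving rows; conflicting many-to-one rows
#' are excluded on both sides and reported.
#'
#' @param probes_a,probes_b Character vectors of probe IDs per platform.
#' @param table Data frame or matrix whose first two columns are
#'   (probe on A, probe on B).
#' @return Data frame with columns `probe_a`, `probe_b`; attribute `excluded`
#'   holds the rows removed by the one-to-one rule.
#' @export
match_probes <- function(probes_a, probes_b, table) {
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  colnames(tab)[1:2] <- c("probe_a", "probe_b")
  tab <- tab[, c("probe_a", "probe_b")]
  present <- tab$probe_a %in% probes_a & tab$probe_b %in% probes_b
  tab <- tab[present, , drop = FALSE]
  conflict <- tab$probe_a %in% tab$probe_a[duplicated(tab$probe_a)] |
    tab$probe_b %in% tab$probe_b[duplicated(tab$probe_b)]
  excluded <- tab[conflict, , drop = FALSE]
  kept <- tab[!conflict, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    message(sprintf("match_probes: excluded %d row(s) violating the one-to-one rule", nrow(excluded)))
  }
  if (nrow(kept) == 0L) warning("match_probes: empty probe map")
  rownames(kept) <- NULL
  attr(kept, "excluded") <- excluded
  kept
}

#' Handle missing cells in a platform matrix
#'
#' `drop_samples` removes every row containing a missing value (the policy
#' used at evaluation time); `error` refuses missing data outright (the policy
#' used at training time).
#'
#' @param x Numeric matrix.
#' @param policy `"drop_samples"` or `"error"`.
#' @return The matrix with complete rows only (policy `drop_samples`).
#' @export
drop_or_impute_missing <- function(x, policy = c("drop_samples", "error")) {
  policy <- match.arg(policy)
  miss <- rowSums(is.na(x)) > 0
  if (!any(miss)) return(x)
  if (policy == "error") {
    stop(sprintf("%d missing value(s) in %d sample row(s); missing data are not allowed here",
                 sum(is.na(x)), sum(miss)))
  }
  message(sprintf("drop_or_impute_missing: dropped %d of %d samples containing missing values",
                  sum(miss), nrow(x)))
  x[!miss, , drop = FALSE]
}

#' Read a pipeline configuration from YAML
#'
#' A flat YAML file can carry any of the options the pipeline understands
#' (file paths, `network_config()` fields, `train_config()` fields, split
#' fractions, seeds); unknown keys are preserved for the caller.
#'
#' @param path YAML file path.
#' @return Named list of options.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  cfg
}

# RNG bookkeeping: library code never clobbers the caller's RNG state.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
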