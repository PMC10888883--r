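# Quality assessment and curation of feature tables. Every operation is a
# pure transform: it validates its own preconditions, never mutates its
# input, and returns a new table with an updated provenance tag, so steps
# chain in any order. All correlation/PCA computations run on log10(x + 1);
# raw intensities are never log-transformed in place.

log10p <- function(x) log10(x + 1)

retag <- function(table, tag) {
  table$provenance_tag <- tag
  table
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Per-acquisition quality metrics
#'
#' Computes, for each acquisition: the feature count (number of nonzero
#' intensities), the TIC (summed intensity), and the median Pearson
#' correlation against all other acquisitions on log10(x+1) intensities —
#' plus a z-score for each metric across acquisitions.
#'
#' @param table a `FeatureTable` with at least 2 acquisitions.
#' @return data.frame with one row per acquisition: `acquisition`,
#'   `feature_count`, `tic`, `median_correlation` and their `z_*` columns.
#' @export
acquisition_metrics <- function(table) {
  n <- length(table$acquisitions)
  if (n < 2) stop("acquisition_metrics requires >= 2 acquisitions")
  X <- table$intensities[, table$acquisitions, drop = FALSE]
  feature_count <- colSums(X > 0)
  tic <- colSums(X)
  L <- log10p(X)
  cm <- suppressWarnings(cor(L))
  cm[!is.finite(cm)] <- 0
  med_cor <- vapply(seq_len(n), function(i) median(cm[-i, i]), 0.0)
  data.frame(
    acquisition = table$acquisitions,
    feature_count = as.numeric(feature_count),
    tic = tic,
    median_correlation = med_cor,
    z_feature_count = zscore(feature_count),
    z_tic = zscore(tic),
    z_median_correlation = zscore(med_cor),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect failed acquisitions
#'
#' Flags acquisitions whose feature-count z-score falls below the threshold
#' (a failed injection loses most of its features, making it an extreme
#' negative outlier).
#'
#' @param metrics data.frame from [acquisition_metrics()].
#' @param z_threshold flag when `z_feature_count < z_threshold` (default -2).
#' @return data.frame of flagged acquisitions with their z values.
#' @export
detect_failed_acquisitions <- function(metrics, z_threshold = -2) {
  flagged <- metrics[metrics$z_feature_count < z_threshold,
                     c("acquisition", "feature_count", "z_feature_count")]
  row.names(flagged) <- NULL
  flagged
}

#' Drop acquisitions from a feature table
#'
#' @param table a `FeatureTable`.
#' @param ids acquisition ids to remove.
#' @return new `FeatureTable` without those columns.
#' @export
drop_acquisitions <- function(table, ids) {
  keep <- setdiff(table$acquisitions, ids)
  if (!length(keep)) stop("dropping all acquisitions")
  table$intensities <- table$intensities[, keep, drop = FALSE]
  table$acquisitions <- keep
  retag(table, "acquisitions_dropped")
}

#' TIC normalization to the median sample TIC
#'
#' Each acquisition is scaled by `median(TICs) / TIC_s`, so every
#' post-normalization TIC equals the original median (the median of an even
#' number of TICs is the mean of the two central values). Idempotent: a
#' second pass is the identity.
#'
#' @param table a `FeatureTable`; all TICs must be > 0.
#' @param reference only `"median"` is supported.
#' @return new `FeatureTable`; per-sample factors in attribute `"factors"`.
#' @export
tic_normalize <- function(table, reference = "median") {
  reference <- match.arg(reference, "median")
  tics <- colSums(table$intensities[, table$acquisitions, drop = FALSE])
  if (any(tics <= 0))
    stop("zero-TIC acquisition(s): ",
         paste(table$acquisitions[tics <= 0], collapse = ", "),
         " (remove failed injections first)")
  factors <- median(tics) / tics
  table$intensities <- sweep(table$intensities[, table$acquisitions,
                                               drop = FALSE],
                             2, factors, `*`)
  out <- retag(table, "normalized")
  attr(out, "factors") <- factors
  out
}

#' Blank masking
#'
#' Drops features whose study-sample signal is not convincingly above the
#' signal in process blanks: a feature is removed iff
#' `aggregator(study) < ratio_k * aggregator(blank)`. Blank columns are
#' removed from the surviving table.
#'
#' @param table a `FeatureTable`.
#' @param blank_ids acquisition ids of the blanks (must be nonempty and
#'   present).
#' @param ratio_k required study-to-blank signal ratio (default 3).
#' @param aggregator `"mean"` or `"max"`.
#' @return new `FeatureTable` without blank columns; dropped feature ids in
#'   attribute `"dropped"`.
#' @export
blank_mask <- function(table, blank_ids, ratio_k = 3,
                       aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  if (!length(blank_ids)) stop("blank_ids must be nonempty")
  missing <- setdiff(blank_ids, table$acquisitions)
  if (length(missing))
    stop("unknown blank acquisition(s): ", paste(missing, collapse = ", "))
  study_ids <- setdiff(table$acquisitions, blank_ids)
  agg <- function(M) if (aggregator == "mean") rowMeans(M)
                     else apply(M, 1, max)
  sb <- agg(table$intensities[, blank_ids, drop = FALSE])
  ss <- agg(table$intensities[, study_ids, drop = FALSE])
  drop <- ss < ratio_k * sb
  out <- table
  out$features <- table$features[!drop, , drop = FALSE]
  out$intensities <- table$intensities[!drop, study_ids, drop = FALSE]
  out$acquisitions <- study_ids
  out <- retag(out, "blank_masked")
  attr(out, "dropped") <- table$features$id[drop]
  out
}

#' Remove rare features
#'
#' Keeps a feature iff it is nonzero in at least
#' `ceiling(min_fraction * n_samples)` of the given samples.
#'
#' @param table a `FeatureTable`.
#' @param min_fraction required detection fraction in `[0, 1]` (default
#'   0.25).
#' @param sample_ids samples over which detection is counted (default: all
#'   acquisitions in the table; pass the study samples to ignore pools).
#' @return new `FeatureTable`; dropped ids in attribute `"dropped"`.
#' @export
drop_rare_features <- function(table, min_fraction = 0.25,
                               sample_ids = table$acquisitions) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  need <- ceiling(min_fraction * length(sample_ids))
  nz <- rowSums(table$intensities[, sample_ids, drop = FALSE] > 0)
  keep <- nz >= need
  out <- table
  out$features <- table$features[keep, , drop = FALSE]
  out$intensities <- table$intensities[keep, , drop = FALSE]
  out <- retag(out, "rare_dropped")
  attr(out, "dropped") <- table$features$id[!keep]
  out
}

#' Impute missing (zero) intensities
#'
#' `half_min_feature`: zeros are replaced by half the smallest nonzero
#' intensity of that feature. Requires every feature to have at least one
#' nonzero value (run [drop_rare_features()] first).
#'
#' @param table a `FeatureTable`.
#' @param method only `"half_min_feature"`.
#' @return new `FeatureTable` with no zeros.
#' @export
impute_missing <- function(table, method = "half_min_feature") {
  method <- match.arg(method, "half_min_feature")
  X <- table$intensities
  allzero <- rowSums(X > 0) == 0
  if (any(allzero))
    stop("all-zero feature(s): ",
         paste(table$features$id[allzero], collapse = ", "),
         " (run drop_rare_features first)")
  for (i in seq_len(nrow(X))) {
    z <- X[i, ] == 0
    if (any(z)) X[i, z] <- min(X[i, !z]) / 2
  }
  table$intensities <- X
  retag(table, "imputed")
}

# ---- batch correction ------------------------------------------------------

# Parametric empirical-Bayes location/scale batch correction on
# log10(x + 1) intensities: feature-wise standardization against the
# batch-design fit, per-batch location (gamma) and scale (delta^2)
# estimates, shrinkage toward batch-level normal / inverse-gamma priors
# fitted by method of moments, iterative joint solution, adjustment and
# de-standardization, then back-transform to the raw scale.

eb_prior_a <- function(d2) {
  m <- mean(d2); s2 <- var(d2)
  (2 * s2 + m^2) / s2
}

eb_prior_b <- function(d2) {
  m <- mean(d2); s2 <- var(d2)
  (m * s2 + m^3) / s2
}

eb_iterate <- function(Z_b, g_hat, d2_hat, g_bar, t2, a, b, conv = 1e-4) {
  n_b <- ncol(Z_b)
  g_old <- g_hat; d_old <- d2_hat
  repeat {
    g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
    ss <- rowSums((Z_b - g_new)^2)
    d_new <- (0.5 * ss + b) / (n_b / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_old, delta2_star = d_old)
}

#' Empirical-Bayes batch correction
#'
#' Parametric location/scale batch correction of a feature table. Intensity
#' values are log10(x+1)-transformed internally, corrected, and
#' back-transformed (never below zero) on output. Requires >= 2 batches
#' with >= 2 samples each; features constant across all samples are passed
#' through unadjusted with a warning.
#'
#' @param table a `FeatureTable`.
#' @param batch_labels character vector of batch labels, one per acquisition
#'   (in `table$acquisitions` order), or a named vector.
#' @param parametric only the parametric variant is implemented.
#' @return new `FeatureTable`; attribute `"batch_model"` holds the per-batch
#'   location/scale estimates (`gamma_hat` on the log scale, raw and
#'   shrunken, and `delta2_star`).
#' @export
combat_correct <- function(table, batch_labels, parametric = TRUE) {
  if (!parametric) stop("only the parametric variant is implemented")
  acqs <- table$acquisitions
  if (!is.null(names(batch_labels))) batch_labels <- batch_labels[acqs]
  batch_labels <- as.character(batch_labels)
  if (length(batch_labels) != length(acqs))
    stop("need one batch label per acquisition")
  batches <- split(seq_along(acqs), batch_labels)
  if (length(batches) < 2) stop("batch correction requires >= 2 batches")
  small <- names(batches)[vapply(batches, length, 0L) < 2]
  if (length(small))
    stop("batch(es) with a single sample: ", paste(small, collapse = ", "))

  X <- log10p(table$intensities[, acqs, drop = FALSE])
  n <- ncol(X)
  const <- apply(X, 1, function(r) max(r) - min(r) == 0)
  if (any(const))
    warning(sum(const), " constant feature(s) passed through unadjusted")
  live <- which(!const)
  Xl <- X[live, , drop = FALSE]

  batch_means <- vapply(batches, function(idx)
    rowMeans(Xl[, idx, drop = FALSE]), numeric(length(live)))
  batch_means <- matrix(batch_means, nrow = length(live),
                        dimnames = list(NULL, names(batches)))
  props <- vapply(batches, length, 0L) / n
  grand <- as.vector(batch_means %*% props)
  fitted <- batch_means[, batch_labels, drop = FALSE]
  var_pooled <- rowSums((Xl - fitted)^2) / n
  var_pooled[var_pooled <= 0] <- min(var_pooled[var_pooled > 0])
  Z <- (Xl - grand) / sqrt(var_pooled)

  model <- list()
  Zc <- Z
  for (b in names(batches)) {
    idx <- batches[[b]]
    Zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d2_hat <- apply(Zb, 1, var)
    d2_hat[d2_hat <= 0] <- 1e-8
    sol <- eb_iterate(Zb, g_hat, d2_hat,
                      g_bar = mean(g_hat), t2 = var(g_hat),
                      a = eb_prior_a(d2_hat), b = eb_prior_b(d2_hat))
    Zc[, idx] <- (Zb - sol$gamma_star) / sqrt(sol$delta2_star)
    model[[b]] <- list(gamma_hat = g_hat * sqrt(var_pooled),
                       gamma_star = sol$gamma_star * sqrt(var_pooled),
                       delta2_star = sol$delta2_star)
  }
  Xc <- Zc * sqrt(var_pooled) + grand

  out_log <- X
  out_log[live, ] <- Xc
  out <- table
  out$intensities <- pmax(10^out_log - 1, 0)
  dimnames(out$intensities) <- dimnames(table$intensities)
  out <- retag(out, "batch_corrected")
  attr(out, "batch_model") <- model
  out
}

# ---- ordination / clustering summaries ------------------------------------

#' PCA summary of a feature table
#'
#' PCA of acquisitions on log10(x+1), feature-centered. Component signs are
#' fixed (largest-magnitude loading positive) so coordinates are
#' deterministic.
#'
#' @param table a `FeatureTable` with >= 2 acquisitions.
#' @param n_components number of components to return (default 2; capped at
#'   the matrix rank).
#' @return list with `coordinates` (acquisitions x components),
#'   `explained_variance` (fractions, non-increasing), and `loadings`.
#' @export
pca_summary <- function(table, n_components = 2) {
  if (length(table$acquisitions) < 2) stop("PCA requires >= 2 acquisitions")
  L <- t(log10p(table$intensities[, table$acquisitions, drop = FALSE]))
  p <- prcomp(L, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}

#' Sample correlation matrix with clustering order
#'
#' Pearson correlation between acquisitions on log10(x+1), hierarchically
#' clustered with average linkage on distance 1 - r.
#'
#' @param table a `FeatureTable` with >= 2 acquisitions.
#' @return list with `correlation` (symmetric, unit diagonal) and
#'   `leaf_order` (acquisition names in dendrogram order).
#' @export
correlation_clustermap_data <- function(table) {
  if (length(table$acquisitions) < 2) stop("requires >= 2 acquisitions")
  L <- log10p(table$intensities[, table$acquisitions, drop = FALSE])
  cm <- suppressWarnings(cor(L))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  hc <- hclust(as.dist(1 - cm), method = "average")
  list(correlation = cm, leaf_order = table$acquisitions[hc$order])
}
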