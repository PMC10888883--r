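eq_table <- function(n_feat = 6, n_samp = 4) {
  # identical (but non-constant) intensity profiles in every sample
  profile <- seq(100, by = 35, length.out = n_feat)
  new_feature_table(
    data.frame(id = sprintf("F%d", 1:n_feat),
               mz = seq(100, by = 50, length.out = n_feat),
               rtime = seq(60, by = 60, length.out = n_feat)),
    matrix(profile, n_feat, n_samp,
           dimnames = list(NULL, sprintf("s%d", 1:n_samp))),
    sprintf("s%d", 1:n_samp))
}

test_that("acquisition metrics on identical samples: r = 1, z = 0", {
  m <- acquisition_metrics(eq_table())
  expect_equal(m$median_correlation, rep(1, 4), tolerance = 1e-12)
  expect_true(all(m$z_feature_count == 0))
  expect_true(all(m$z_tic == 0))
  expect_error(acquisition_metrics(
    new_feature_table(data.frame(id = "F1", mz = 100, rtime = 1),
                      matrix(1, 1, 1, dimnames = list(NULL, "s1")), "s1")),
    ">= 2")
})

test_that("feature-count z-scores isolate the low sample", {
  counts <- c(1000, 1010, 990, 100)
  tb <- new_feature_table(
    data.frame(id = sprintf("F%04d", 1:1010),
               mz = runif(1010, 80, 900), rtime = runif(1010, 30, 1200)),
    vapply(counts, function(k) c(rep(100, k), rep(0, 1010 - k)),
           numeric(1010)) |>
      (\(m) {colnames(m) <- sprintf("s%d", 1:4); m})(),
    sprintf("s%d", 1:4))
  m <- acquisition_metrics(tb)
  expect_equal(m$acquisition[which.min(m$z_feature_count)], "s4")
  expect_lt(min(m$z_feature_count), -1.4)
  # z-scores standardized across acquisitions
  expect_equal(mean(m$z_feature_count), 0, tolerance = 1e-12)
  expect_equal(sd(m$z_feature_count), 1, tolerance = 1e-12)
})

test_that("failed-injection detection flags the planted dropout uniquely", {
  for (seed in c(1, 2)) {
    g <- generate_feature_experiment(n_compounds = 25, n_samples = 20,
                                     seed = seed, failed_samples = 1,
                                     failed_fraction = 0.9)
    m <- acquisition_metrics(g$table)
    flagged <- detect_failed_acquisitions(m, z_threshold = -2)
    expect_equal(flagged$acquisition, g$ground_truth$failed_samples)
    # threshold monotonicity: an extreme threshold flags nothing
    expect_equal(nrow(detect_failed_acquisitions(m, z_threshold = -10)), 0)
  }
  expect_equal(nrow(detect_failed_acquisitions(
    acquisition_metrics(eq_table()), -2)), 0)
})

test_that("TIC normalization: factors, equal medians, idempotence, errors", {
  tb <- new_feature_table(
    data.frame(id = c("F1", "F2"), mz = c(100, 200), rtime = c(10, 20)),
    matrix(c(40, 60, 100, 200), 2, 2, dimnames = list(NULL, c("s1", "s2"))),
    c("s1", "s2"))
  nt <- tic_normalize(tb)                       # TICs 100, 300 -> median 200
  expect_equal(unname(attr(nt, "factors")), c(2, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(colSums(nt$intensities)), c(200, 200),
               tolerance = 1e-9 * 200)
  # already equal -> all factors 1; idempotence
  nt2 <- tic_normalize(nt)
  expect_equal(unname(attr(nt2, "factors")), c(1, 1), tolerance = 1e-12)
  expect_equal(nt2$intensities, nt$intensities, tolerance = 1e-12)
  # zero-TIC error names the sample
  tb$intensities[, 2] <- 0
  expect_error(tic_normalize(tb), "s2")
})

test_that("blank masking drops by the k-fold rule and removes blank columns", {
  tb <- new_feature_table(
    data.frame(id = c("contam", "clean", "absent"),
               mz = c(100, 200, 300), rtime = c(10, 20, 30)),
    matrix(c(250, 900, 50,          # study s1
             250, 900, 50,          # study s2
             100, 10, 0),           # blank b1
           3, 3, dimnames = list(NULL, c("s1", "s2", "b1"))),
    c("s1", "s2", "b1"))
  out <- blank_mask(tb, "b1", ratio_k = 3)
  expect_equal(attr(out, "dropped"), "contam")    # 250 < 3 * 100
  expect_setequal(out$features$id, c("clean", "absent"))
  expect_equal(out$acquisitions, c("s1", "s2"))
  # k = 0 drops nothing
  expect_length(attr(blank_mask(tb, "b1", ratio_k = 0), "dropped"), 0)
  # monotone in k
  n_kept <- function(k) nrow(blank_mask(tb, "b1", ratio_k = k)$features)
  expect_gte(n_kept(1), n_kept(3))
  expect_gte(n_kept(3), n_kept(10))
  expect_error(blank_mask(tb, character(0)), "nonempty")
  expect_error(blank_mask(tb, "zz"), "unknown blank")
})

test_that("rare-feature removal uses the ceiling rule and is monotone", {
  X <- matrix(0, 2, 10, dimnames = list(NULL, sprintf("s%d", 1:10)))
  X[1, 1] <- 5            # present in 1/10
  X[2, ] <- 7             # ubiquitous
  tb <- new_feature_table(
    data.frame(id = c("rare", "common"), mz = c(100, 200), rtime = c(1, 2)),
    X, sprintf("s%d", 1:10))
  out <- drop_rare_features(tb, min_fraction = 0.25)  # ceil(2.5) = 3 > 1
  expect_equal(out$features$id, "common")
  expect_equal(nrow(drop_rare_features(tb, 0)$features), 2)    # identity
  expect_equal(drop_rare_features(tb, 1)$features$id, "common")
  expect_gte(nrow(drop_rare_features(tb, 0.1)$features),
             nrow(drop_rare_features(tb, 0.5)$features))
})

test_that("imputation replaces zeros by half the feature minimum", {
  tb <- new_feature_table(
    data.frame(id = "F1", mz = 100, rtime = 10),
    matrix(c(0, 10, 20), 1, 3, dimnames = list(NULL, c("a", "b", "c"))),
    c("a", "b", "c"))
  out <- impute_missing(tb)
  expect_equal(unname(out$intensities[1, ]), c(5, 10, 20))
  # no zeros -> identity; then drop_rare is identity too
  expect_equal(impute_missing(out)$intensities, out$intensities)
  expect_equal(nrow(drop_rare_features(out, 0.9)$features), 1)
  tb$intensities[1, ] <- 0
  expect_error(impute_missing(tb), "all-zero")
})

test_that("batch correction recovers planted effects and reduces differences", {
  sim <- simulate_batch_table(n_features = 50, n_samples = 20, shift = 1.0,
                              scale = 1.5, seed = 7)
  out <- combat_correct(sim$table, sim$batch_labels)
  expect_equal(dim(out$intensities), dim(sim$table$intensities))
  l0 <- log10(sim$table$intensities + 1)
  l1 <- log10(out$intensities + 1)
  b1 <- names(sim$batch_labels)[sim$batch_labels == "B1"]
  b2 <- names(sim$batch_labels)[sim$batch_labels == "B2"]
  d0 <- rowMeans(l0[, b2]) - rowMeans(l0[, b1])
  d1 <- rowMeans(l1[, b2]) - rowMeans(l1[, b1])
  expect_gte(1 - mean(abs(d1)) / mean(abs(d0)), 0.90)
  bm <- attr(out, "batch_model")
  est <- bm$B2$gamma_hat - bm$B1$gamma_hat
  expect_gt(cor(est, sim$ground_truth[, "B2"]), 0.9)
})

test_that("batch correction edge cases: labels, single batch, null effects", {
  sim <- simulate_batch_table(seed = 4)
  expect_error(combat_correct(sim$table,
                              rep("B1", length(sim$batch_labels))),
               ">= 2 batches")
  bad <- sim$batch_labels
  bad[1] <- "B3"
  expect_error(combat_correct(sim$table, bad), "single sample")
  # zero planted effect: output stays close to input relative to data sd
  null_sim <- simulate_batch_table(shift = 0, shift_sd = 0, scale = 1,
                                   seed = 9)
  out <- combat_correct(null_sim$table, null_sim$batch_labels)
  l0 <- log10(null_sim$table$intensities + 1)
  l1 <- log10(out$intensities + 1)
  expect_lt(max(abs(l1 - l0)), 0.5 * sd(l0))
})

test_that("constant features pass through batch correction unadjusted", {
  sim <- simulate_batch_table(n_features = 10, seed = 5)
  sim$table$intensities[3, ] <- 42
  expect_warning(out <- combat_correct(sim$table, sim$batch_labels),
                 "constant feature")
  expect_equal(unname(out$intensities[3, ]),
               rep(42, ncol(out$intensities)), tolerance = 1e-9)
})

test_that("PCA: single varying feature, duplicates, reconstruction", {
  tb <- eq_table(n_feat = 5, n_samp = 4)
  tb$intensities[3, ] <- c(10, 1000, 10, 1000)
  p <- pca_summary(tb, 2)
  expect_equal(p$explained_variance[1], 1.0, tolerance = 1e-12)
  # duplicated sample set -> coincident points
  tb2 <- tb
  tb2$intensities <- cbind(tb$intensities, tb$intensities)
  colnames(tb2$intensities) <- sprintf("s%d", 1:8)
  tb2$acquisitions <- sprintf("s%d", 1:8)
  p2 <- pca_summary(tb2, 2)
  expect_equal(unname(p2$coordinates[1, ]), unname(p2$coordinates[5, ]),
               tolerance = 1e-9)
  # full-rank reconstruction matches centered data
  set.seed(2)
  tb3 <- new_feature_table(
    data.frame(id = sprintf("F%d", 1:50), mz = runif(50, 80, 900),
               rtime = runif(50, 30, 1200)),
    matrix(rlnorm(500, 10, 1), 50, 10,
           dimnames = list(NULL, sprintf("s%d", 1:10))),
    sprintf("s%d", 1:10))
  p3 <- pca_summary(tb3, n_components = 10)
  L <- t(log10(tb3$intensities + 1))
  centered <- scale(L, center = TRUE, scale = FALSE)
  recon <- p3$coordinates %*% t(p3$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_true(all(diff(p3$explained_variance) <= 1e-12))
  expect_lte(sum(p3$explained_variance), 1 + 1e-12)
  # deterministic sign convention
  expect_identical(pca_summary(tb3, 2)$coordinates, p3$coordinates[, 1:2])
})

test_that("correlation clustermap: identical pair adjacent, determinism", {
  set.seed(5)
  base <- rlnorm(30, 8, 1)
  X <- cbind(a = base, b = base, c = rev(base) * runif(30, 0.5, 2))
  tb <- new_feature_table(
    data.frame(id = sprintf("F%d", 1:30), mz = runif(30, 80, 900),
               rtime = runif(30, 30, 1200)),
    X, c("a", "b", "c"))
  cc <- correlation_clustermap_data(tb)
  expect_equal(diag(cc$correlation), c(a = 1, b = 1, c = 1))
  expect_equal(cc$correlation, t(cc$correlation))
  ia <- match("a", cc$leaf_order); ib <- match("b", cc$leaf_order)
  expect_equal(abs(ia - ib), 1)           # identical samples adjacent
  expect_identical(correlation_clustermap_data(tb)$leaf_order, cc$leaf_order)
  # all-identical samples -> matrix of ones
  cc2 <- correlation_clustermap_data(eq_table())
  expect_equal(unname(cc2$correlation), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("QC transforms are pure: input table untouched, provenance updated", {
  tb <- eq_table()
  before <- unname(tb$intensities)
  nt <- tic_normalize(tb)
  expect_equal(unname(tb$intensities), before)
  expect_equal(nt$provenance_tag, "normalized")
  expect_equal(impute_missing(tb)$provenance_tag, "imputed")
  expect_equal(drop_rare_features(tb)$provenance_tag, "rare_dropped")
})
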