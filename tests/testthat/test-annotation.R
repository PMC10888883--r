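glucose_mass <- 180.0633881   # C6H12O6 monoisotopic

test_that("level 4 attaches all isomers within tolerance, with ppm evidence", {
  ec <- toy_empcpd()                       # neutral mass 180.0633776
  cl <- list(new_compound("glc", "glucose", "C6H12O6", glucose_mass),
             new_compound("fru", "fructose", "C6H12O6", glucose_mass),
             new_compound("x", "faraway", "C2H2", 26.0156))
  out <- annotate_level4(list(ec), cl, mz_tol_ppm = 5)
  anns <- out[[1]]$annotations
  expect_length(anns, 2)
  expect_setequal(vapply(anns, `[[`, "", "compound_name"),
                  c("glucose", "fructose"))
  expect_true(all(vapply(anns, function(a)
    abs(a$evidence$ppm_error) < 1, TRUE)))
  expect_true(all(vapply(anns, `[[`, "", "level") == "4"))
})

test_that("level 4 skips compounds without neutral mass; tol 0 is exact-only", {
  ec <- toy_empcpd()
  ec$neutral_formula_mass <- NA_real_
  out <- annotate_level4(list(ec), list(new_compound("g", "g", "C", 180.06)),
                         mz_tol_ppm = 5)
  expect_length(out[[1]]$annotations, 0)

  ec2 <- toy_empcpd()
  ec2$neutral_formula_mass <- glucose_mass
  cl <- list(new_compound("exact", "exact", "C6H12O6", glucose_mass),
             new_compound("near", "near", "C6H12O6", glucose_mass + 1e-4))
  out2 <- annotate_level4(list(ec2), cl, mz_tol_ppm = 0)
  expect_equal(vapply(out2[[1]]$annotations, `[[`, "", "compound_name"),
               "exact")
  expect_warning(annotate_level4(list(ec2), list()), "empty")
})

test_that("level 1b requires both m/z and rt gates; ranking by combined error", {
  ec <- toy_empcpd()   # member F1 at (181.0706541, 100 s)
  std <- data.frame(name = c("hit", "rt_off", "close2"),
                    mz = c(181.0706, 181.0706, 181.0710),
                    rtime = c(101, 200, 100.5))
  out <- annotate_level1b(list(ec), std, mz_tol_ppm = 10, rt_tol_s = 5)
  anns <- out[[1]]$annotations
  expect_setequal(vapply(anns, `[[`, "", "compound_name"),
                  c("hit", "close2"))   # rt_off excluded by the rt gate
  expect_true(all(vapply(anns, `[[`, "", "level") == "1b"))
  expect_true(all(vapply(anns, function(a)
    !is.null(a$evidence$rt_error_s) && !is.null(a$evidence$ppm_error), TRUE)))
})

test_that("precursor index equals linear scan, including closed boundaries", {
  set.seed(33)
  refs <- lapply(1:300, function(i)
    new_ref_spectrum(paste0("c", i), runif(1, 100, 900), cbind(100, 1)))
  idx <- build_precursor_index(refs, mz_tol_ppm = 10)
  for (q in runif(200, 100, 900))
    expect_equal(sort(idx$precursor[query_precursor_index(idx, q)]),
                 sort(vapply(oracle_precursor_scan(refs, q, 10),
                             function(i) refs[[i]]$precursor_mz, 0.0)))
  # boundary: q exactly at mz * (1 + tol) is included
  mz0 <- 500
  idx2 <- build_precursor_index(list(new_ref_spectrum("b", mz0, cbind(1, 1))),
                                mz_tol_ppm = 10)
  expect_equal(query_precursor_index(idx2, mz0 * (1 + 10e-6)), 1L)
  expect_equal(query_precursor_index(idx2, mz0 * (1 - 10e-6)), 1L)
  expect_length(query_precursor_index(idx2, mz0 * (1 + 10.5e-6)), 0)
  # empty library
  idx3 <- build_precursor_index(list(), 10)
  expect_length(query_precursor_index(idx3, 500), 0)
  # refs lacking precursor excluded with count
  refs2 <- c(refs[1:2], list(new_ref_spectrum("nop", NA, cbind(1, 1))))
  expect_equal(attr(build_precursor_index(refs2, 10), "n_unindexed"), 1L)
})

test_that("cosine score: identity, disjoint, and the hand-computed case", {
  a <- cbind(c(100, 150), c(1.0, 0.25))
  expect_equal(cosine_score(a, a, 0.01)$score, 1.0, tolerance = 1e-12)
  expect_equal(cosine_score(a, a, 0.01)$n_matched, 2L)
  d <- cosine_score(cbind(100, 1), cbind(200, 1), 0.01)
  expect_equal(d$score, 0.0)
  expect_equal(d$n_matched, 0L)
  b <- cbind(c(100, 150), c(0.25, 1.0))
  r <- cosine_score(a, b, 0.01)
  expect_equal(r$score, 0.64, tolerance = 1e-12)   # (0.5+0.5)^2 / 1.5625
  expect_error(cosine_score(a, matrix(numeric(0), ncol = 2), 0.01), "empty")
})

test_that("cosine score is symmetric and scale-invariant (property)", {
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- cbind(sort(runif(n1, 50, 500)), runif(n1, 1, 100))
    b <- cbind(sort(runif(n2, 50, 500)), runif(n2, 1, 100))
    if (runif(1) < 0.5) b[seq_len(min(n1, n2)), 1] <-
        a[seq_len(min(n1, n2)), 1] + rnorm(min(n1, n2), 0, 0.004)
    s_ab <- cosine_score(a, b, 0.01)
    s_ba <- cosine_score(b, a, 0.01)
    expect_equal(s_ab$score, s_ba$score, tolerance = 1e-12)
    expect_equal(s_ab$n_matched, s_ba$n_matched)
    sc <- cosine_score(a, cbind(b[, 1], b[, 2] * 37.5), 0.01)
    expect_equal(sc$score, s_ab$score, tolerance = 1e-12)
    expect_true(s_ab$score >= 0 && s_ab$score <= 1)
    expect_lte(s_ab$n_matched, min(n1, n2))
  }
})

test_that("greedy pairing matches brute-force optimum on most small spectra", {
  set.seed(123)
  n_total <- 0L; n_agree <- 0L
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- cbind(sort(runif(n1, 50, 120)), runif(n1, 1, 100))
    b <- cbind(sort(runif(n2, 50, 120)), runif(n2, 1, 100))
    g <- cosine_score(a, b, 2)$score     # wide tolerance forces conflicts
    o <- oracle_cosine_optimal(a, b, 2)
    n_total <- n_total + 1L
    if (abs(g - o) <= 1e-9) n_agree <- n_agree + 1L
    expect_lte(g, o + 1e-9)              # greedy never beats the optimum
  }
  expect_gte(n_agree / n_total, 0.95)
})

test_that("MS2 spectra map to the empirical compound within both windows", {
  ec1 <- toy_empcpd("ec_00001")
  sp <- new_ms_spectrum(cbind(c(85, 127), c(10, 5)), 2L,
                        precursor_mz = 181.0708, retention_time = 110)
  far <- new_ms_spectrum(cbind(100, 1), 2L, precursor_mz = 500,
                         retention_time = 110)
  res <- map_ms2_to_empcpds(list(sp, far), list(ec1))
  expect_length(res$empcpds[[1]]$ms2_spectra, 1)
  expect_length(res$unmatched, 1)
  expect_equal(res$unmatched[[1]]$precursor_mz, 500)
})

test_that("nearest empirical compound wins a contested spectrum", {
  ec1 <- toy_empcpd("ec_00001")                  # F1 @ rt 100
  ec2 <- toy_empcpd("ec_00002")
  ec2$ms1_features$rtime <- c(125, 125.2)        # further in rt
  sp <- new_ms_spectrum(cbind(85, 10), 2L, precursor_mz = 181.0706541,
                        retention_time = 103)
  res <- map_ms2_to_empcpds(list(sp), list(ec2, ec1))
  expect_length(res$empcpds[[2]]$ms2_spectra, 1)  # ec1 (rt 100) wins
  expect_length(res$empcpds[[1]]$ms2_spectra, 0)
})

test_that("MS2 annotation levels: authentic -> 1a, external -> 2; idempotent", {
  peaks <- cbind(c(85.02, 127.04, 163.06), c(100, 40, 20))
  ref_auth <- new_ref_spectrum("glucose", 181.0706541, peaks,
                               source_library = "inhouse",
                               is_authentic_standard = TRUE)
  ref_ext <- new_ref_spectrum("glucose", 181.0706541, peaks,
                              source_library = "public")
  ec <- toy_empcpd()
  ec$ms2_spectra <- list(new_ms_spectrum(peaks, 2L,
                                         precursor_mz = 181.0706541,
                                         retention_time = 100))
  out <- annotate_level2_1a(list(ec), list(ref_auth, ref_ext),
                            min_matched = 3L)
  lv <- vapply(out[[1]]$annotations, `[[`, "", "level")
  expect_setequal(lv, c("1a", "2"))
  expect_equal(out[[1]]$annotations[[1]]$level, "1a")   # sorted first
  expect_equal(out[[1]]$annotations[[1]]$score, 1.0, tolerance = 1e-12)
  # annotating again with the same source adds nothing
  out2 <- annotate_level2_1a(out, list(ref_auth, ref_ext), min_matched = 3L)
  expect_length(out2[[1]]$annotations, 2)
  expect_warning(annotate_level2_1a(out, list()), "empty")
})

test_that("level invariants hold after every annotate_* call", {
  g <- generate_spectral_library(5, 6, seed = 8)
  ec <- toy_empcpd()
  ec$ms2_spectra <- g$queries[1]
  ecs <- annotate_level4(list(ec),
                         list(new_compound("glc", "glucose", "C6H12O6",
                                           glucose_mass)), 5)
  ecs <- annotate_level1b(ecs, data.frame(name = "std", mz = 181.0706,
                                          rtime = 100.5))
  ecs <- annotate_level2_1a(ecs, g$refs)
  for (a in ecs[[1]]$annotations)
    expect_length(metquilt:::validate_annotation(a), 0)
})

test_that("jittered queries recover their reference (20-compound library)", {
  g <- generate_spectral_library(n_compounds = 20, peaks_per_spectrum = 8,
                                 seed = 3)
  top1 <- 0L
  for (i in seq_along(g$queries)) {
    scores <- vapply(g$refs, function(r)
      cosine_score(g$queries[[i]], r, 0.01)$score, 0.0)
    if (g$refs[[which.max(scores)]]$compound_name == g$ground_truth[i] &&
        max(scores) >= 0.6)
      top1 <- top1 + 1L
  }
  expect_gte(top1, 19L)
})
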