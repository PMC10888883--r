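# Synthetic data generators with ground truth. These emulate the aligned
# feature tables, metadata, MS2 libraries and mzML files the pipeline
# consumes — not raw scan data. All generators are seed-deterministic and
# return the planted truth needed to score recovery exactly.
#
# Default noise magnitudes (1 ppm m/z, 0.5 s retention-time jitter, 5%
# intensity jitter) are realistic for orbitrap-class instruments while
# keeping planted structure recoverable at the pipeline's default
# tolerances.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
           else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic feature-table experiment with ground truth
#'
#' Plants `n_compounds` compounds (neutral mass ~ U(80, 900) Da, retention
#' time ~ U(30, 1200) s), each expressed as an anchor adduct plus a random
#' subset of further adducts and isotopologues at the exact relation deltas,
#' with optional m/z noise (sigma = 1 ppm) and retention-time jitter
#' (sigma = 0.5 s). Intensities are log-normal with per-sample variation;
#' per-batch, per-feature location shifts (log10 scale) are applied when
#' `n_batches > 1`; optional blanks carry 5% of the study signal; optional
#' failed injections have a fraction of their features zeroed. Optional
#' unrelated noise features are appended.
#'
#' @param n_compounds number of planted compounds.
#' @param n_samples number of study samples.
#' @param n_batches number of batches (labels `B1`, `B2`, ...).
#' @param ion_mode `"pos"` or `"neg"`.
#' @param seed RNG seed.
#' @param noise apply m/z + rt noise (`FALSE` = exact deltas).
#' @param mz_noise_ppm,rt_jitter_s noise magnitudes.
#' @param n_blanks number of process blanks (5% carryover intensity).
#' @param n_noise_features unrelated singleton features to append.
#' @param failed_samples names (or count) of samples simulated as failed
#'   injections.
#' @param failed_fraction fraction of features zeroed in a failed sample.
#' @param batch_shift_sd sd of per-feature log10 batch location shifts.
#' @return list with `table` (`FeatureTable`), `acquisitions` (list of
#'   `Acquisition`), and `ground_truth` (planted memberships with tags,
#'   per-batch/per-feature shifts, failed-injection ids, noise feature ids).
#' @export
generate_feature_experiment <- function(n_compounds = 12, n_samples = 6,
                                        n_batches = 1, ion_mode = "pos",
                                        seed = 1, noise = TRUE,
                                        mz_noise_ppm = 1, rt_jitter_s = 0.5,
                                        n_blanks = 0, n_noise_features = 0,
                                        failed_samples = 0,
                                        failed_fraction = 0.9,
                                        batch_shift_sd = 0.2) {
  stopifnot(n_compounds >= 1, n_samples >= 1, n_batches >= 1)
  with_seed(seed, {
    relations <- default_relation_table(ion_mode)
    ad <- relation_adducts(relations)
    ad <- ad[ad$charge == 1L, ]
    anchor <- ad$label[ad$anchor][1]

    sample_names <- sprintf("S%02d", seq_len(n_samples))
    blank_names <- if (n_blanks > 0) sprintf("BL%02d", seq_len(n_blanks))
                   else character(0)
    all_names <- c(sample_names, blank_names)
    batch_of <- rep(sprintf("B%d", seq_len(n_batches)),
                    length.out = n_samples)
    if (is.numeric(failed_samples) && length(failed_samples) == 1)
      failed_samples <- if (failed_samples >= 1)
        sample(sample_names, failed_samples) else character(0)

    feats <- list(); truth <- list()
    fid <- 0L
    intens <- list()
    for (ci in seq_len(n_compounds)) {
      M <- runif(1, 80, 900)
      rt <- runif(1, 30, 1200)
      n_adducts <- sample(1:3, 1)
      adducts <- unique(c(anchor, sample(ad$label, n_adducts)))
      n_iso <- sample(1:3, 1)           # M0 .. M+(n_iso-1)
      base_log <- rnorm(1, log(5e5), 1)
      members <- character(0); tags <- list()
      planned <- list()
      for (a in adducts) {
        for (k in seq_len(n_iso) - 1L) {
          # require the anchor M0 cell; other cells present at random
          if (!(a == anchor && k == 0L) && runif(1) < 0.2) next
          planned[[length(planned) + 1L]] <- list(a = a, k = k)
        }
      }
      # a grid needs at least two occupied cells: force the anchor M+1
      if (length(planned) < 2L)
        planned[[2L]] <- list(a = anchor, k = 1L)
      a_fracs <- stats::setNames(
        ifelse(adducts == anchor, 1, runif(length(adducts), 0.2, 0.8)),
        adducts)
      for (cell in planned) {
        a <- cell$a; k <- cell$k
        a_frac <- a_fracs[[a]]
        {
          fid <- fid + 1L
          id <- sprintf("F%04d", fid)
          mz <- cell_mz(M, k, ad$delta_mz[ad$label == a], 1L)
          frt <- rt
          if (noise) {
            mz <- mz + rnorm(1, 0, mz_noise_ppm * 1e-6 * mz)
            frt <- frt + rnorm(1, 0, rt_jitter_s)
          }
          k_frac <- c(1, 0.25, 0.06, 0.015)[k + 1L]
          base <- exp(base_log) * a_frac * k_frac
          row <- exp(rnorm(n_samples, 0, 0.3)) * base
          feats[[id]] <- data.frame(id = id, mz = mz, rtime = frt,
                                    stringsAsFactors = FALSE)
          intens[[id]] <- row
          members <- c(members, id)
          tags[[id]] <- c(isotope = ISOTOPE_LABELS[k + 1L], modification = a)
        }
      }
      truth[[sprintf("C%03d", ci)]] <- list(
        neutral_mass = M, rtime = rt, members = members, tags = tags)
    }
    noise_ids <- character(0)
    for (ni in seq_len(n_noise_features)) {
      fid <- fid + 1L
      id <- sprintf("F%04d", fid)
      feats[[id]] <- data.frame(id = id, mz = runif(1, 80, 950),
                                rtime = runif(1, 30, 1200),
                                stringsAsFactors = FALSE)
      intens[[id]] <- exp(rnorm(n_samples, 0, 0.3)) * exp(rnorm(1, log(1e5), 1))
      noise_ids <- c(noise_ids, id)
    }
    features <- do.call(rbind, feats)
    X <- do.call(rbind, intens)
    dimnames(X) <- list(features$id, sample_names)

    # per-batch, per-feature location shifts on log10 scale
    batch_effects <- NULL
    if (n_batches > 1) {
      batch_effects <- matrix(0, nrow(X), n_batches,
                              dimnames = list(features$id,
                                              sprintf("B%d", seq_len(n_batches))))
      for (b in 2:n_batches)
        batch_effects[, b] <- rnorm(nrow(X), 0, batch_shift_sd)
      for (s in seq_len(n_samples)) {
        b <- match(batch_of[s], colnames(batch_effects))
        X[, s] <- 10^(log10(X[, s] + 1) + batch_effects[, b]) - 1
      }
    }

    # failed injections: zero a fraction of the sample's features
    for (s in failed_samples) {
      kill <- sample(nrow(X), round(failed_fraction * nrow(X)))
      X[kill, s] <- 0
    }

    if (n_blanks > 0) {
      carry <- vapply(seq_len(n_blanks), function(i)
        rowMeans(X[, sample_names, drop = FALSE]) * 0.05 *
          exp(rnorm(nrow(X), 0, 0.2)), numeric(nrow(X)))
      X <- cbind(X, matrix(carry, nrow(X),
                           dimnames = list(NULL, blank_names)))
    }

    acqs <- c(
      lapply(seq_len(n_samples), function(i) new_acquisition(
        sample_names[i], filepath = paste0(sample_names[i], ".mzML"),
        sample_type = "study", batch = batch_of[i])),
      lapply(blank_names, function(b) new_acquisition(
        b, filepath = paste0(b, ".mzML"), sample_type = "blank",
        batch = "B1")))
    table <- new_feature_table(features, X, all_names,
                               provenance_tag = "synthetic")
    list(table = table, acquisitions = acqs,
         ground_truth = list(compounds = truth,
                             batch_effects = batch_effects,
                             batch_of = stats::setNames(batch_of, sample_names),
                             failed_samples = failed_samples,
                             noise_features = noise_ids))
  })
}

#' Generate a synthetic MS2 spectral library plus jittered queries
#'
#' Reference spectra are random fragment ladders below a random precursor;
#' each query is a copy of one reference with multiplicative intensity
#' jitter (sigma = 5%), one randomly dropped peak, and a precursor within
#' 2 ppm. The ground truth maps each query to its source compound.
#'
#' @param n_compounds number of reference spectra.
#' @param peaks_per_spectrum fragments per reference (>= 3).
#' @param seed RNG seed.
#' @param intensity_jitter_sd multiplicative intensity jitter sd.
#' @param n_dropped_peaks peaks removed from each query.
#' @param precursor_jitter_ppm query precursor deviation, ppm.
#' @param rt_range retention times assigned to queries (s).
#' @return list with `refs` (list of `RefSpectrum`), `queries` (list of MS2
#'   `MSSpectrum`), and `ground_truth` (query index -> compound name).
#' @export
generate_spectral_library <- function(n_compounds = 20,
                                      peaks_per_spectrum = 8, seed = 1,
                                      intensity_jitter_sd = 0.05,
                                      n_dropped_peaks = 1,
                                      precursor_jitter_ppm = 2,
                                      rt_range = c(60, 1100)) {
  stopifnot(peaks_per_spectrum >= 3)
  with_seed(seed, {
    refs <- list(); queries <- list(); truth <- character(0)
    for (i in seq_len(n_compounds)) {
      name <- sprintf("SYN_CPD_%03d", i)
      prec <- runif(1, 150, 800)
      mzs <- sort(runif(peaks_per_spectrum, 50, prec - 1))
      ints <- exp(rnorm(peaks_per_spectrum, log(100), 1))
      refs[[i]] <- new_ref_spectrum(name, prec, cbind(mzs, ints),
                                    source_library = "synthetic_library")
      keep <- sort(sample(peaks_per_spectrum,
                          peaks_per_spectrum - n_dropped_peaks))
      q_int <- ints[keep] * exp(rnorm(length(keep), 0, intensity_jitter_sd))
      q_prec <- prec * (1 + runif(1, -1, 1) * precursor_jitter_ppm * 1e-6)
      queries[[i]] <- new_ms_spectrum(
        cbind(mzs[keep], q_int), ms_level = 2L, precursor_mz = q_prec,
        retention_time = runif(1, rt_range[1], rt_range[2]),
        source_acquisition = "synthetic_query")
      truth[i] <- name
    }
    list(refs = refs, queries = queries, ground_truth = truth)
  })
}

#' Simulate a feature table with planted batch effects
#'
#' Log10-scale intensities N(mu_f, sigma_f) per feature, with per-feature
#' location shifts (mean `shift`, sd `shift_sd`) and a scale inflation
#' (`scale`) applied to every batch beyond the first. Used to validate
#' batch correction against known truth.
#'
#' @param n_features,n_samples table dimensions.
#' @param n_batches number of batches, samples split evenly.
#' @param shift mean per-feature log10 location shift of batch 2+.
#' @param shift_sd sd of the per-feature shifts.
#' @param scale multiplicative sd inflation in batch 2+.
#' @param seed RNG seed.
#' @return list with `table`, `batch_labels` (named by acquisition), and
#'   `ground_truth` (matrix of planted per-feature shifts per batch).
#' @export
simulate_batch_table <- function(n_features = 50, n_samples = 20,
                                 n_batches = 2, shift = 1.0, shift_sd = 0.5,
                                 scale = 1.5, seed = 1) {
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    batch_labels <- stats::setNames(
      rep(sprintf("B%d", seq_len(n_batches)), length.out = n_samples),
      samples)
    mu <- runif(n_features, 3, 6)
    sigma <- runif(n_features, 0.2, 0.5)
    shifts <- matrix(0, n_features, n_batches,
                     dimnames = list(NULL, sprintf("B%d", seq_len(n_batches))))
    for (b in 2:n_batches) shifts[, b] <- rnorm(n_features, shift, shift_sd)
    L <- matrix(0, n_features, n_samples, dimnames = list(NULL, samples))
    for (s in seq_len(n_samples)) {
      b <- match(batch_labels[s], colnames(shifts))
      sc <- if (b > 1) scale else 1
      L[, s] <- rnorm(n_features, mu + shifts[, b], sigma * sc)
    }
    features <- data.frame(id = sprintf("F%04d", seq_len(n_features)),
                           mz = runif(n_features, 80, 900),
                           rtime = runif(n_features, 30, 1200),
                           stringsAsFactors = FALSE)
    table <- new_feature_table(features, pmax(10^L - 1, 0), samples,
                               provenance_tag = "synthetic_batch")
    list(table = table, batch_labels = batch_labels,
         ground_truth = shifts)
  })
}
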