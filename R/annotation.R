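# Multi-level annotation. Level semantics used throughout this package, in
# the spirit of the Schymanski confidence scheme:
#   1a — MS2 similarity match against an authentic-standard spectral library
#   1b — m/z + retention-time match to an authentic chemical standard
#   2  — MS2 similarity match against an external spectral library
#   4  — neutral-mass-only match against a compound list (does not resolve
#        isomers: all candidates within tolerance are attached)
# ppm is 1e6 * delta_m / m, computed against the reference m/z; ppm windows
# are closed intervals.

ppm_window <- function(mz, ppm) c(mz * (1 - ppm * 1e-6), mz * (1 + ppm * 1e-6))

# de-duplication key for chained annotation (idempotence)
ann_key <- function(a) paste(a$source, a$compound_name, a$level, sep = "\r")

attach_annotation <- function(ec, ann) {
  keys <- vapply(ec$annotations, ann_key, "")
  if (ann_key(ann) %in% keys) {
    # keep the better-scoring record for the same (source, compound, level)
    i <- which(keys == ann_key(ann))[1]
    old <- ec$annotations[[i]]
    old_s <- if (is.null(old$score)) -Inf else old$score
    new_s <- if (is.null(ann$score)) -Inf else ann$score
    if (new_s > old_s) ec$annotations[[i]] <- ann
  } else {
    ec$annotations[[length(ec$annotations) + 1L]] <- ann
  }
  ec$annotations <- sort_annotations(ec$annotations)
  ec
}

#' Read a compound list for neutral-mass annotation
#'
#' CSV with columns `name`, `formula` (optional), `neutral_mono_mass`
#' (or `mono_mass`/`mass`).
#'
#' @param path CSV path.
#' @return list of [new_compound()] objects.
#' @export
read_compound_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mass_col <- intersect(c("neutral_mono_mass", "mono_mass", "mass"), names(df))
  if (!length(mass_col)) stop("compound list needs a neutral mass column")
  if (!"name" %in% names(df)) stop("compound list needs a 'name' column")
  lapply(seq_len(nrow(df)), function(i) new_compound(
    id = if ("id" %in% names(df)) as.character(df$id[i]) else df$name[i],
    name = df$name[i],
    formula = if ("formula" %in% names(df)) df$formula[i] else NA_character_,
    neutral_mono_mass = df[[mass_col[1]]][i]))
}

#' Read an authentic-standards table
#'
#' CSV with columns `name`, `mz`, `rtime`; any other columns become
#' identifier entries.
#'
#' @param path CSV path.
#' @return data.frame with columns `name`, `mz`, `rtime` plus identifiers.
#' @export
read_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "mz", "rtime"), names(df))
  if (length(miss))
    stop("standards table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$mz <= 0) || any(df$rtime < 0))
    stop("standards require mz > 0 and rtime >= 0")
  df
}

#' Level-4 annotation by neutral-mass lookup
#'
#' For every empirical compound with an inferred neutral mass, attaches all
#' compounds from the list whose neutral monoisotopic mass lies within the
#' closed ppm window. Isomers are not resolved at this level: every match is
#' attached, with the signed ppm error recorded as evidence.
#'
#' @param empcpds list of `EmpiricalCompound`.
#' @param compound_list list of [new_compound()] entries.
#' @param mz_tol_ppm mass tolerance, ppm (against the reference mass).
#' @param source annotation source label.
#' @return updated list of empirical compounds.
#' @export
annotate_level4 <- function(empcpds, compound_list, mz_tol_ppm = 5,
                            source = "compound_list") {
  if (!length(compound_list)) {
    warning("empty compound list; level-4 annotation is a no-op")
    return(empcpds)
  }
  ref_mass <- vapply(compound_list, `[[`, 0.0, "neutral_mono_mass")
  lapply(empcpds, function(ec) {
    M <- ec$neutral_formula_mass
    if (!is.finite(M)) return(ec)
    err_ppm <- (M - ref_mass) / ref_mass * 1e6
    hits <- which(abs(err_ppm) <= mz_tol_ppm)
    for (h in hits) {
      cpd <- compound_list[[h]]
      ids <- list()
      if (!is.na(cpd$formula)) ids$formula <- cpd$formula
      ids$id <- cpd$id
      ec <- attach_annotation(ec, new_annotation(
        "4", cpd$name, identifiers = ids, source = source,
        evidence = list(ppm_error = err_ppm[h], reference_mass = ref_mass[h])))
    }
    ec
  })
}

#' Level-1b annotation against authentic standards
#'
#' A member feature matches a standard iff the ppm error (against the
#' standard's m/z) is within `mz_tol_ppm` and the absolute retention-time
#' error is within `rt_tol_s`. Matches are attached to the feature's
#' empirical compound with both errors as evidence; multiple standards in
#' the window are all attached, ranked by combined normalized error
#' `(ppm/ppm_tol)^2 + (rt/rt_tol)^2`.
#'
#' @param empcpds list of `EmpiricalCompound`.
#' @param standards data.frame from [read_standards()].
#' @param mz_tol_ppm m/z tolerance, ppm (default 10).
#' @param rt_tol_s retention-time tolerance, seconds (default 5).
#' @param source annotation source label.
#' @return updated list of empirical compounds.
#' @export
annotate_level1b <- function(empcpds, standards, mz_tol_ppm = 10,
                             rt_tol_s = 5, source = "authentic_standards") {
  lapply(empcpds, function(ec) {
    for (i in seq_len(nrow(ec$ms1_features))) {
      fmz <- ec$ms1_features$mz[i]
      frt <- ec$ms1_features$rtime[i]
      ppm <- (fmz - standards$mz) / standards$mz * 1e6
      drt <- frt - standards$rtime
      hits <- which(abs(ppm) <= mz_tol_ppm & abs(drt) <= rt_tol_s)
      if (!length(hits)) next
      comb <- (ppm[hits] / mz_tol_ppm)^2 + (drt[hits] / rt_tol_s)^2
      hits <- hits[order(comb, standards$name[hits])]
      for (h in hits) {
        ids <- as.list(standards[h, setdiff(names(standards),
                                            c("name", "mz", "rtime")),
                       drop = FALSE])
        ec <- attach_annotation(ec, new_annotation(
          "1b", standards$name[h], identifiers = ids, source = source,
          evidence = list(ppm_error = ppm[h], rt_error_s = drt[h],
                          feature_id = ec$ms1_features$feature_id[i])))
      }
    }
    ec
  })
}

# ---- precursor index -------------------------------------------------------

#' Build a precursor m/z index over a spectral library
#'
#' Sorted index over reference precursor m/z supporting logarithmic point
#' queries: `query_precursor_index(idx, q)` returns exactly the references
#' with `|q - precursor| <= ppm window of the reference precursor` (closed
#' interval) — identical to an exhaustive linear scan, which the test suite
#' verifies. References lacking a precursor m/z are excluded, with the count
#' reported via the `"n_unindexed"` attribute.
#'
#' @param refs list of `RefSpectrum`.
#' @param mz_tol_ppm ppm half-width of each reference's window.
#' @return object of class `PrecursorIndex`.
#' @export
build_precursor_index <- function(refs, mz_tol_ppm = 10) {
  prec <- vapply(refs, function(r) as.numeric(r$precursor_mz)[1], 0.0)
  ok <- is.finite(prec)
  n_unindexed <- sum(!ok)
  refs <- refs[ok]; prec <- prec[ok]
  ord <- order(prec)
  idx <- structure(list(
    refs = refs[ord],
    precursor = prec[ord],
    lo = prec[ord] * (1 - mz_tol_ppm * 1e-6),
    hi = prec[ord] * (1 + mz_tol_ppm * 1e-6),
    mz_tol_ppm = mz_tol_ppm
  ), class = "PrecursorIndex")
  attr(idx, "n_unindexed") <- n_unindexed
  idx
}

#' Query a precursor index
#'
#' @param index a `PrecursorIndex`.
#' @param q query m/z.
#' @return integer positions into `index$refs` of all matching references.
#' @export
query_precursor_index <- function(index, q) {
  if (!length(index$precursor)) return(integer(0))
  # windows are proportional to precursor, so lo and hi are both sorted;
  # candidates have lo <= q and hi >= q.
  last <- findInterval(q, index$lo)           # lo[1..last] <= q
  if (last == 0) return(integer(0))
  # hi is sorted ascending: first position with hi >= q
  first <- findInterval(q, index$hi, left.open = TRUE) + 1L
  if (first > last) return(integer(0))
  first:last
}

# ---- spectral similarity ---------------------------------------------------

#' Modified cosine similarity between two centroided spectra
#'
#' Square-root intensity transform, then greedy peak pairing: candidate
#' pairs are peaks within `frag_tol_da`, directly or after shifting the
#' second spectrum's m/z by `precursor_shift`; pairs are taken in descending
#' intensity-product order, each peak used at most once. The score is
#' `(sum sqrt(Ia*Ib))^2 / (sum Ia * sum Ib)` over matched pairs — the cosine
#' of the sqrt-intensity vectors under the chosen pairing — and lies in
#' [0, 1].
#'
#' @param a,b spectra: `MSSpectrum`/`RefSpectrum` objects or two-column
#'   (mz, intensity) matrices.
#' @param frag_tol_da fragment m/z tolerance in Da (default 0.01).
#' @param precursor_shift precursor mass difference in Da to allow as an
#'   alternative alignment (0 = plain cosine).
#' @return list with `score` and `n_matched`.
#' @export
cosine_score <- function(a, b, frag_tol_da = 0.01, precursor_shift = 0) {
  pa <- if (is.matrix(a)) a else a$peaks
  pb <- if (is.matrix(b)) b else b$peaks
  if (!nrow(pa) || !nrow(pb)) stop("cosine_score: empty spectrum")
  stopifnot(frag_tol_da > 0)
  sa <- sqrt(pa[, 2]); sb <- sqrt(pb[, 2])
  # candidate pairs
  dm <- outer(pa[, 1], pb[, 1], `-`)
  ok <- abs(dm) <= frag_tol_da
  if (precursor_shift != 0) ok <- ok | (abs(dm + precursor_shift) <= frag_tol_da)
  cand <- which(ok, arr.ind = TRUE)
  if (!nrow(cand)) return(list(score = 0.0, n_matched = 0L))
  prod <- sa[cand[, 1]] * sb[cand[, 2]]
  ord <- order(-prod, cand[, 1], cand[, 2])
  used_a <- logical(length(sa)); used_b <- logical(length(sb))
  acc <- 0.0; n_matched <- 0L
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    acc <- acc + prod[k]
    n_matched <- n_matched + 1L
  }
  score <- acc^2 / (sum(sa^2) * sum(sb^2))
  list(score = min(1.0, score), n_matched = n_matched)
}

# ---- MS2 mapping and annotation -------------------------------------------

#' Map experimental MS2 spectra onto empirical compounds
#'
#' A spectrum is attached to the empirical compound that has a member
#' feature within both the precursor ppm window and the retention-time
#' window (defaults 10 ppm / 30 s, suitable for MS1 and MS2 runs acquired
#' separately). When several compounds qualify, the one minimizing the
#' combined normalized distance `(ppm/ppm_tol)^2 + (rt/rt_tol)^2` wins;
#' remaining ties break by interim id. Unmatched spectra are returned
#' separately.
#'
#' @param spectra list of MS2 `MSSpectrum`.
#' @param empcpds list of `EmpiricalCompound`.
#' @param mz_tol_ppm precursor tolerance, ppm (default 10).
#' @param rt_tol_s retention-time tolerance, seconds (default 30).
#' @return list with `empcpds` (updated) and `unmatched` (list of spectra).
#' @export
map_ms2_to_empcpds <- function(spectra, empcpds, mz_tol_ppm = 10,
                               rt_tol_s = 30) {
  feat <- do.call(rbind, lapply(seq_along(empcpds), function(i) {
    f <- empcpds[[i]]$ms1_features
    data.frame(ec = i, mz = f$mz, rtime = f$rtime, stringsAsFactors = FALSE)
  }))
  unmatched <- list()
  for (sp in spectra) {
    if (is.null(feat)) { unmatched[[length(unmatched) + 1L]] <- sp; next }
    ppm <- (sp$precursor_mz - feat$mz) / feat$mz * 1e6
    drt <- sp$retention_time - feat$rtime
    hits <- which(abs(ppm) <= mz_tol_ppm & abs(drt) <= rt_tol_s)
    if (!length(hits)) {
      unmatched[[length(unmatched) + 1L]] <- sp
      next
    }
    comb <- (ppm[hits] / mz_tol_ppm)^2 + (drt[hits] / rt_tol_s)^2
    ec_ids <- vapply(feat$ec[hits], function(i) empcpds[[i]]$interim_id, "")
    best <- hits[order(comb, ec_ids)][1]
    ec_i <- feat$ec[best]
    empcpds[[ec_i]]$ms2_spectra <-
      c(empcpds[[ec_i]]$ms2_spectra, list(sp))
  }
  list(empcpds = empcpds, unmatched = unmatched)
}

#' MS2 similarity annotation (levels 2 and 1a)
#'
#' Scores every MS2 spectrum attached to each empirical compound against
#' library references retrieved through a precursor index; matches passing
#' both the score and matched-peak thresholds are attached as level `"1a"`
#' when the reference is an authentic standard, else `"2"`. For multiple
#' spectra hitting the same reference the best score is kept.
#'
#' @param empcpds list of `EmpiricalCompound` carrying MS2 spectra.
#' @param library list of `RefSpectrum`.
#' @param frag_tol_da fragment tolerance, Da (default 0.01).
#' @param min_score minimum similarity score (default 0.60).
#' @param min_matched minimum number of matched peaks (default 3).
#' @param precursor_ppm ppm window for candidate retrieval (default 10).
#' @param source annotation source label; defaults to each reference's
#'   `source_library`.
#' @return updated list of empirical compounds.
#' @export
annotate_level2_1a <- function(empcpds, library, frag_tol_da = 0.01,
                               min_score = 0.60, min_matched = 3L,
                               precursor_ppm = 10, source = NULL) {
  if (!length(library)) {
    warning("empty spectral library; MS2 annotation is a no-op")
    return(empcpds)
  }
  index <- build_precursor_index(library, precursor_ppm)
  lapply(empcpds, function(ec) {
    if (!length(ec$ms2_spectra)) return(ec)
    best_by_ref <- list()
    for (sp in ec$ms2_spectra) {
      if (!nrow(sp$peaks)) next
      for (pos in query_precursor_index(index, sp$precursor_mz)) {
        ref <- index$refs[[pos]]
        res <- cosine_score(sp, ref, frag_tol_da)
        if (res$score >= min_score && res$n_matched >= min_matched) {
          key <- paste(ref$source_library, ref$compound_name, sep = "\r")
          if (is.null(best_by_ref[[key]]) ||
              res$score > best_by_ref[[key]]$res$score)
            best_by_ref[[key]] <- list(ref = ref, res = res, sp = sp)
        }
      }
    }
    for (m in best_by_ref) {
      lvl <- if (m$ref$is_authentic_standard) "1a" else "2"
      ids <- list()
      if (!is.na(m$ref$formula)) ids$formula <- m$ref$formula
      ppm_err <- (m$sp$precursor_mz - m$ref$precursor_mz) /
        m$ref$precursor_mz * 1e6
      ec <- attach_annotation(ec, new_annotation(
        lvl, m$ref$compound_name, identifiers = ids, score = m$res$score,
        source = if (is.null(source)) m$ref$source_library else source,
        evidence = list(n_matched_peaks = m$res$n_matched,
                        ppm_error = ppm_err)))
    }
    ec
  })
}
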