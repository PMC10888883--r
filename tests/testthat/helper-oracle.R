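# Independent brute-force oracles. These deliberately share no code with the
# implementation paths they check.

# ---- exhaustive relation-consistent grouping (instances <= 12 features) ----

# Can the features in `idx` be placed injectively on one grid? Tries every
# (root, root-adduct) hypothesis; membership requires |rt - rt_root| <=
# rt_tol and a distinct (isotope, adduct) cell within ppm tolerance.
oracle_subset_consistent <- function(feats, idx, relations, ppm, rt_tol,
                                     max_iso = 3L) {
  ad <- relations[relations$kind == "adduct", , drop = FALSE]
  for (r in idx) {
    for (ai in seq_len(nrow(ad))) {
      z <- ad$charge[ai]
      M <- z * feats$mz[r] - ad$delta_mz[ai]
      if (M <= 0) next
      cols <- ad[ad$charge == z, , drop = FALSE]
      # candidate cells per feature
      cells <- lapply(idx, function(f) {
        if (abs(feats$rtime[f] - feats$rtime[r]) > rt_tol) return(integer(0))
        hits <- integer(0)
        cell_id <- 0L
        for (ci in seq_len(nrow(cols))) for (k in 0:max_iso) {
          cell_id <- cell_id + 1L
          mz_cell <- (M + cols$delta_mz[ci]) / z + k * 1.0033548 / z
          if (abs(feats$mz[f] - mz_cell) <= ppm * 1e-6 * feats$mz[f])
            hits <- c(hits, cell_id)
        }
        hits
      })
      if (any(vapply(cells, length, 0L) == 0)) next
      # injective assignment via backtracking
      assign_ok <- function(i, used) {
        if (i > length(cells)) return(TRUE)
        for (cell in cells[[i]]) {
          if (cell %in% used) next
          if (assign_ok(i + 1L, c(used, cell))) return(TRUE)
        }
        FALSE
      }
      if (assign_ok(1L, integer(0))) return(TRUE)
    }
  }
  FALSE
}

all_subsets <- function(n, min_size = 2L) {
  out <- list()
  for (m in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) >= min_size) out[[length(out) + 1L]] <- idx
  }
  out
}

# Exhaustive search over partitions into relation-consistent groups,
# maximizing (grouped feature count, then within-group pair count).
oracle_group <- function(table, relations, ppm = 5, rt_tol = 2) {
  feats <- table$features
  n <- nrow(feats)
  stopifnot(n <= 12)
  cand <- Filter(function(s)
    oracle_subset_consistent(feats, s, relations, ppm, rt_tol),
    all_subsets(n))
  best <- list(score = c(-1, -1), groups = list())
  pack <- function(remaining_cand, used, covered, pairs, groups) {
    score <- c(covered, pairs)
    if (score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2]))
      best <<- list(score = score, groups = groups)
    for (ci in seq_along(remaining_cand)) {
      s <- remaining_cand[[ci]]
      if (any(s %in% used)) next
      pack(remaining_cand[-seq_len(ci)], c(used, s),
           covered + length(s), pairs + choose(length(s), 2),
           c(groups, list(s)))
    }
  }
  pack(cand, integer(0), 0L, 0L, list())
  lapply(best$groups, function(s) sort(feats$id[s]))
}

# ---- optimal-pairing spectral similarity (<= 6 peaks) ----------------------

oracle_cosine_optimal <- function(pa, pb, tol, shift = 0) {
  sa <- sqrt(pa[, 2]); sb <- sqrt(pb[, 2])
  cand <- which(outer(pa[, 1], pb[, 1], function(x, y)
    abs(x - y) <= tol | (shift != 0 & abs(x - y + shift) <= tol)),
    arr.ind = TRUE)
  best <- 0
  rec <- function(k, used_a, used_b, acc) {
    if (acc > best) best <<- acc
    if (k > nrow(cand)) return()
    rec(k + 1L, used_a, used_b, acc)                 # skip pair k
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% used_a) && !(j %in% used_b))
      rec(k + 1L, c(used_a, i), c(used_b, j), acc + sa[i] * sb[j])
  }
  if (nrow(cand)) rec(1L, integer(0), integer(0), 0)
  min(1, best^2 / (sum(sa^2) * sum(sb^2)))
}

# ---- linear-scan precursor lookup -----------------------------------------

oracle_precursor_scan <- function(refs, q, ppm) {
  prec <- vapply(refs, function(r) as.numeric(r$precursor_mz)[1], 0.0)
  which(is.finite(prec) & abs(q - prec) <= ppm * 1e-6 * prec)
}
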