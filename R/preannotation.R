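# Pre-annotation: grouping of degenerate features (isotopologues, adducts)
# into empirical-compound grids and neutral-mass inference.
#
# The grid model: rows are isotopologue labels (M0, 13C/12C, 13C/12C*2, ...)
# at 1.0033548/z Da spacing, columns are adduct labels; each occupied cell is
# one feature. A grid is anchored at a hypothesised neutral mass M, and cell
# m/z values are M/z + adduct contribution + k * 1.0033548 / z.

ISOTOPE_LABELS <- c("M0", "13C/12C", "13C/12C*2", "13C/12C*3")
MAX_ISOTOPES <- 3L

#' Default isotope/adduct mass-relation table
#'
#' Charge-adjusted m/z deltas from standard atomic masses. Positive mode:
#' anchor [M+H]+ (+1.0072765 vs neutral), plus [M+Na]+, [M+NH4]+, [M+K]+.
#' Negative mode: anchor [M-H]- (-1.0072765), plus [M+Cl]-, [M+formate]-,
#' [M+Na-2H]-. Isotopologue rows M0..M+3 at 1.0033548 Da spacing (divided by
#' z at use time; the spacing itself is ion-mode independent).
#'
#' @param ion_mode `"pos"` or `"neg"`.
#' @return data.frame with columns `label`, `kind` (isotope/adduct),
#'   `delta_mz` (Da, vs the neutral molecule for adducts; vs M0 for
#'   isotopes), `anchor` (logical), `charge`.
#' @export
default_relation_table <- function(ion_mode = c("pos", "neg")) {
  ion_mode <- match.arg(ion_mode)
  iso <- data.frame(
    label = ISOTOPE_LABELS,
    kind = "isotope",
    delta_mz = (0:MAX_ISOTOPES) * C13_C12_DELTA,
    anchor = c(TRUE, FALSE, FALSE, FALSE),
    charge = 1L, stringsAsFactors = FALSE)
  adducts <- if (ion_mode == "pos") data.frame(
    label = c("M+H[1+]", "M+NH4[1+]", "M+Na[1+]", "M+K[1+]", "M+2H[2+]"),
    kind = "adduct",
    # deltas vs neutral M: proton; +NH4 = M+H + 17.0265491; +Na = M+H +
    # 21.9819443; +K = M+H + 37.9558820; [M+2H]2+ carries 2 protons at z=2.
    delta_mz = c(PROTON_MASS, PROTON_MASS + 17.0265491,
                 PROTON_MASS + 21.9819443, PROTON_MASS + 37.9558820,
                 2 * PROTON_MASS),
    anchor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    charge = c(1L, 1L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  else data.frame(
    label = c("M-H[-]", "M+Na-2H[-]", "M+Cl[-]", "M+HCOO[-]", "M-2H[2-]"),
    kind = "adduct",
    delta_mz = c(-PROTON_MASS, -PROTON_MASS + 21.9819443,
                 -PROTON_MASS + 35.9766549, -PROTON_MASS + 46.0054793,
                 -2 * PROTON_MASS),
    anchor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    charge = c(1L, 1L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  out <- rbind(iso, adducts)
  attr(out, "ion_mode") <- ion_mode
  out
}

#' Read a user relation table from CSV
#'
#' Columns: `label`, `kind` (`isotope`/`adduct`), `delta_mz`, `anchor`
#' (logical), optional `charge` (default 1).
#'
#' @param path CSV path.
#' @param ion_mode ion mode recorded on the table.
#' @return relation data.frame as in [default_relation_table()].
#' @export
read_relation_table <- function(path, ion_mode = c("pos", "neg")) {
  ion_mode <- match.arg(ion_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "kind", "delta_mz", "anchor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("relation table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$label))
    stop("duplicate relation label(s): ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  if (is.null(df$charge)) df$charge <- 1L
  df$anchor <- as.logical(df$anchor)
  df$delta_mz <- as.numeric(df$delta_mz)
  attr(df, "ion_mode") <- ion_mode
  df
}

relation_adducts <- function(relations) {
  relations[relations$kind == "adduct", , drop = FALSE]
}

# m/z of grid cell (isotope k, adduct row a) for neutral mass M.
cell_mz <- function(M, k, adduct_delta, z) {
  (M + adduct_delta) / z + k * C13_C12_DELTA / z
}

#' Neutral mass implied by one ion
#'
#' Inverts the adduct relation: `M = z * mz - delta`, where `delta` is the
#' total (signed) mass contribution of the adduct, charge-sign aware.
#'
#' @param mz observed m/z.
#' @param modification adduct label present in `relations`.
#' @param relations relation table.
#' @return neutral monoisotopic mass (Da).
#' @export
neutral_mass_from_ion <- function(mz, modification, relations) {
  ad <- relation_adducts(relations)
  i <- match(modification, ad$label)
  if (is.na(i)) stop("unknown modification label: ", modification)
  ad$charge[i] * mz - ad$delta_mz[i]
}

# All distinct positive m/z deltas between any two z=1 grid cells, plus the
# z=2 isotopologue spacings; used for candidate-edge detection.
candidate_deltas <- function(relations) {
  ad <- relation_adducts(relations)
  a1 <- ad$delta_mz[ad$charge == 1L]
  iso <- (-MAX_ISOTOPES:MAX_ISOTOPES) * C13_C12_DELTA
  d <- as.vector(outer(a1, a1, `-`))
  d <- unique(abs(as.vector(outer(d, iso, `+`))))
  d <- c(d, (1:MAX_ISOTOPES) * C13_C12_DELTA / 2)
  sort(unique(d[d > 1e-9]))
}

# Hypothesis fit: given a root feature (index r) interpreted as cell
# (M0, adduct a0) at charge z, greedily place every other component feature
# in its best grid cell. Conflicts resolve to the smaller ppm error, ties to
# the higher total intensity. Returns NULL or a list(idx, isotope,
# modification, ppm, M, z, score).
fit_grid_hypothesis <- function(feats, r, a0_label, relations, mz_tol_ppm,
                                rt_tol_s) {
  ad <- relation_adducts(relations)
  a0 <- ad[ad$label == a0_label, ]
  z0 <- a0$charge
  M <- z0 * feats$mz[r] - a0$delta_mz
  if (M <= 0) return(NULL)
  cols <- ad[ad$charge == z0, , drop = FALSE]
  # cell table for this hypothesis
  grid <- expand.grid(k = 0:MAX_ISOTOPES, a = seq_len(nrow(cols)))
  grid$mz <- cell_mz(M, grid$k, cols$delta_mz[grid$a], z0)
  assigned_cell <- rep(NA_integer_, nrow(feats))   # feature -> grid row
  cell_owner <- rep(NA_integer_, nrow(grid))       # grid row -> feature
  ppm_err <- rep(NA_real_, nrow(feats))
  cand <- which(abs(feats$rtime - feats$rtime[r]) <= rt_tol_s)
  # visit in deterministic order: by ppm error of the best cell
  best_cell <- integer(0); best_ppm <- numeric(0)
  for (i in cand) {
    err <- abs(feats$mz[i] - grid$mz) / feats$mz[i] * 1e6
    j <- which.min(err)
    if (err[j] <= mz_tol_ppm) {
      best_cell <- c(best_cell, j); best_ppm <- c(best_ppm, err[j])
    } else {
      best_cell <- c(best_cell, NA_integer_); best_ppm <- c(best_ppm, NA_real_)
    }
  }
  ok <- which(!is.na(best_cell))
  for (i in ok[order(best_ppm[ok])]) {
    fi <- cand[i]; cell <- best_cell[i]
    owner <- cell_owner[cell]
    if (is.na(owner)) {
      cell_owner[cell] <- fi
      assigned_cell[fi] <- cell
      ppm_err[fi] <- best_ppm[i]
    } else if (best_ppm[i] < ppm_err[owner] - 1e-12 ||
               (abs(best_ppm[i] - ppm_err[owner]) <= 1e-12 &&
                feats$intensity[fi] > feats$intensity[owner])) {
      assigned_cell[owner] <- NA_integer_
      cell_owner[cell] <- fi
      assigned_cell[fi] <- cell
      ppm_err[fi] <- best_ppm[i]
    }
  }
  idx <- which(!is.na(assigned_cell))
  if (length(idx) < 2L) return(NULL)
  cells <- grid[assigned_cell[idx], ]
  list(idx = idx,
       isotope = ISOTOPE_LABELS[cells$k + 1L],
       modification = cols$label[cells$a],
       ppm = ppm_err[idx],
       M = M, z = z0,
       score = c(length(idx), -sum(ppm_err[idx])))
}

#' Group features into empirical compounds
#'
#' Builds candidate edges between co-eluting features (|delta rt| <=
#' `rt_tol_s`) whose m/z difference matches any relation delta or difference
#' of two deltas within `mz_tol_ppm` of the larger m/z, takes connected
#' components of the edge graph, and resolves each component into one or more
#' isotopologue-by-adduct grids. A feature fitting several grid cells is
#' assigned to the cell minimizing ppm error (ties: higher intensity wins);
#' features fitting no grid become singletons. Every input feature appears
#' exactly once across empirical compounds plus singletons.
#'
#' @param table a `FeatureTable`.
#' @param relations relation table ([default_relation_table()]).
#' @param mz_tol_ppm m/z tolerance, ppm (default 5).
#' @param rt_tol_s co-elution window, seconds (default 2).
#' @return list with `empcpds` (list of `EmpiricalCompound`, ordered by first
#'   member's position in the input table) and `singletons` (character vector
#'   of ungrouped feature ids).
#' @export
build_empirical_compounds <- function(table, relations = NULL,
                                      mz_tol_ppm = 5, rt_tol_s = 2) {
  if (is.null(relations)) relations <- default_relation_table("pos")
  stopifnot(mz_tol_ppm > 0, rt_tol_s >= 0)
  feats <- data.frame(id = table$features$id, mz = table$features$mz,
                      rtime = table$features$rtime,
                      intensity = rowSums(table$intensities),
                      stringsAsFactors = FALSE)
  n <- nrow(feats)
  if (n == 0) return(list(empcpds = list(), singletons = character(0)))
  deltas <- candidate_deltas(relations)
  max_delta <- max(deltas)

  # candidate edges on mz-sorted features
  ord <- order(feats$mz)
  edges_i <- integer(0); edges_j <- integer(0); edges_ppm <- numeric(0)
  for (ii in seq_len(n - 1)) {
    i <- ord[ii]
    for (jj in (ii + 1):n) {
      j <- ord[jj]
      d <- feats$mz[j] - feats$mz[i]
      if (d > max_delta + mz_tol_ppm * 1e-6 * feats$mz[j]) break
      if (abs(feats$rtime[i] - feats$rtime[j]) > rt_tol_s) next
      tol <- mz_tol_ppm * 1e-6 * max(feats$mz[i], feats$mz[j])
      err <- min(abs(d - deltas))
      if (err <= tol) {
        edges_i <- c(edges_i, i); edges_j <- c(edges_j, j)
        edges_ppm <- c(edges_ppm, err / max(feats$mz[i], feats$mz[j]) * 1e6)
      }
    }
  }

  # connected components (union-find)
  parent <- seq_len(n)
  findr <- function(x) { r <- x; while (parent[r] != r) r <- parent[r]; r }
  for (e in seq_along(edges_i)) {
    a <- findr(edges_i[e]); b <- findr(edges_j[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), findr, 0L)

  # oversized-component guard: drop worst-ppm edges until below cap
  ad1 <- relation_adducts(relations)
  cap <- 2L * (MAX_ISOTOPES + 1L) * nrow(ad1)
  keep <- rep(TRUE, length(edges_i))
  repeat {
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes > cap])
    if (!length(big)) break
    in_big <- keep & (comp[edges_i] %in% big)
    if (!any(in_big)) break
    worst <- which(in_big)[which.max(edges_ppm[in_big])]
    keep[worst] <- FALSE
    parent <- seq_len(n)
    for (e in which(keep)) {
      a <- findr(edges_i[e]); b <- findr(edges_j[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_len(n), findr, 0L)
  }

  ion_mode <- attr(relations, "ion_mode")
  charge_sign <- if (identical(ion_mode, "neg")) -1L else 1L
  adduct_labels <- ad1$label

  empcpds <- list()
  singleton_idx <- integer(0)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) {
      singleton_idx <- c(singleton_idx, members)
      next
    }
    remaining <- members
    while (length(remaining) >= 2L) {
      sub <- feats[remaining, , drop = FALSE]
      best <- NULL
      for (ri in seq_len(nrow(sub))) {
        for (a0 in adduct_labels) {
          fit <- fit_grid_hypothesis(sub, ri, a0, relations, mz_tol_ppm,
                                     rt_tol_s)
          if (is.null(fit)) next
          if (is.null(best) ||
              fit$score[1] > best$score[1] ||
              (fit$score[1] == best$score[1] && fit$score[2] > best$score[2] + 1e-12))
            best <- fit
        }
      }
      if (is.null(best)) break
      gi <- remaining[best$idx]
      empcpds[[length(empcpds) + 1L]] <- new_empirical_compound(
        interim_id = sprintf("ec_tmp_%d", length(empcpds) + 1L),
        ms1_features = data.frame(
          feature_id = feats$id[gi], mz = feats$mz[gi],
          rtime = feats$rtime[gi], isotope = best$isotope,
          modification = best$modification, stringsAsFactors = FALSE),
        charge_sign = charge_sign)
      remaining <- setdiff(remaining, gi)
    }
    singleton_idx <- c(singleton_idx, remaining)
  }

  # deterministic ordering by first member's position in the input table
  first_pos <- vapply(empcpds, function(ec)
    min(match(ec$ms1_features$feature_id, feats$id)), 0L)
  empcpds <- empcpds[order(first_pos)]
  for (i in seq_along(empcpds)) {
    empcpds[[i]]$interim_id <- sprintf("ec_%05d", i)
    empcpds[[i]] <- infer_neutral_mass(empcpds[[i]], relations)
  }
  list(empcpds = empcpds,
       singletons = feats$id[sort(singleton_idx)])
}

#' Infer the neutral monoisotopic mass of an empirical compound
#'
#' Averages `z * mz - adduct mass contribution` over the M0 (monoisotopic)
#' member features whose adduct tag is resolvable against the relation
#' table. If no member carries a resolvable adduct tag, the compound is
#' returned with `neutral_formula_mass = NA` and flagged via the
#' `"unresolved"` attribute.
#'
#' @param ec an `EmpiricalCompound`.
#' @param relations relation table.
#' @return the updated `EmpiricalCompound`.
#' @export
infer_neutral_mass <- function(ec, relations = NULL) {
  if (is.null(relations)) relations <- default_relation_table(
    if (ec$charge_sign < 0) "neg" else "pos")
  ad <- relation_adducts(relations)
  m0 <- ec$ms1_features[ec$ms1_features$isotope == "M0", , drop = FALSE]
  m0 <- m0[m0$modification %in% ad$label, , drop = FALSE]
  if (!nrow(m0)) {
    ec$neutral_formula_mass <- NA_real_
    attr(ec, "unresolved") <- TRUE
    return(ec)
  }
  masses <- vapply(seq_len(nrow(m0)), function(i)
    neutral_mass_from_ion(m0$mz[i], m0$modification[i], relations), 0.0)
  ec$neutral_formula_mass <- mean(masses)
  attr(ec, "unresolved") <- NULL
  ec
}
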