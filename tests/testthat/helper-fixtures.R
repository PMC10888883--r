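# Small fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

toy_feature_table <- function() {
  new_feature_table(
    features = data.frame(id = c("F1", "F2", "F3"),
                          mz = c(181.0707, 182.0740, 250.1),
                          rtime = c(100.0, 100.2, 500.0),
                          stringsAsFactors = FALSE),
    intensities = matrix(c(1000, 250, 80,
                           1100, 260, 90),
                         nrow = 3,
                         dimnames = list(NULL, c("s1", "s2"))),
    acquisitions = c("s1", "s2"))
}

toy_tsv <- function(path) {
  writeLines(c(
    "id\tmz\trtime\ts1\ts2",
    "F1\t181.0707\t100\t1000\t1100",
    "F2\t182.074\t100.2\t250\t260",
    "F3\t250.1\t500\t80\t90"), path)
  path
}

# one empirical compound with two features (M0/M+H, 13C/M+H)
toy_empcpd <- function(id = "ec_00001", annotations = list()) {
  new_empirical_compound(
    interim_id = id,
    ms1_features = data.frame(
      feature_id = c("F1", "F2"),
      mz = c(181.0706541, 182.0740089),
      rtime = c(100.0, 100.2),
      isotope = c("M0", "13C/12C"),
      modification = c("M+H[1+]", "M+H[1+]"),
      stringsAsFactors = FALSE),
    charge_sign = 1L,
    neutral_formula_mass = 180.0633776)
}

# random empirical compound generator for round-trip property tests
random_empcpd <- function(i) {
  nf <- sample(1:4, 1)
  iso <- sample(ISOTOPE_LABELS <- c("M0", "13C/12C", "13C/12C*2", "13C/12C*3"),
                nf)
  mods <- sample(c("M+H[1+]", "M+Na[1+]", "M+K[1+]", "M+NH4[1+]"), nf,
                 replace = TRUE)
  while (anyDuplicated(paste(iso, mods))) {
    mods <- sample(c("M+H[1+]", "M+Na[1+]", "M+K[1+]", "M+NH4[1+]"), nf,
                   replace = TRUE)
  }
  ms2 <- if (runif(1) < 0.5) list(new_ms_spectrum(
    cbind(sort(runif(3, 50, 400)), runif(3, 1, 100)), 2L,
    precursor_mz = runif(1, 100, 500), retention_time = runif(1, 0, 1000),
    source_acquisition = "acq1")) else list()
  anns <- if (runif(1) < 0.5) list(
    new_annotation("4", paste0("cpd", i),
                   identifiers = list(formula = "C6H12O6"),
                   source = "listA",
                   evidence = list(ppm_error = runif(1, -5, 5))),
    new_annotation("2", paste0("cpd", i), score = runif(1),
                   source = "libB",
                   evidence = list(n_matched_peaks = 4))) else list()
  new_empirical_compound(
    interim_id = sprintf("ec_%05d", i),
    ms1_features = data.frame(
      feature_id = sprintf("F%d_%d", i, seq_len(nf)),
      mz = sort(runif(nf, 100, 900)),
      rtime = rep(runif(1, 30, 1200), nf),
      isotope = iso, modification = mods, stringsAsFactors = FALSE),
    charge_sign = sample(c(1L, -1L), 1),
    neutral_formula_mass = if (runif(1) < 0.8) runif(1, 80, 900) else NA_real_,
    ms2_spectra = ms2, annotations = anns)
}

msp_text_two_entries <- function(path) {
  writeLines(c(
    "Name: Alpha",
    "PrecursorMZ: 181.0707",
    "Formula: C6H12O6",
    "Num Peaks: 3",
    "85.02 100",
    "59.013 40",
    "127.039 25",
    "",
    "Name: Beta",
    "Num Peaks: 2",
    "90.1 10",
    "120.2 20",
    ""), path)
  path
}

# planted-grid table builder used by grouping tests: exact relation deltas
planted_grid_table <- function(masses, rts, cells_per_cpd, relations,
                               noise_ids = 0) {
  ad <- relations[relations$kind == "adduct" & relations$charge == 1L, ]
  rows <- list(); k <- 0L; truth <- list()
  for (ci in seq_along(masses)) {
    members <- character(0)
    for (cell in cells_per_cpd[[ci]]) {
      k <- k + 1L
      id <- sprintf("F%03d", k)
      mz <- (masses[ci] + ad$delta_mz[ad$label == cell$a]) + cell$k * 1.0033548
      rows[[id]] <- data.frame(id = id, mz = mz, rtime = rts[ci])
      members <- c(members, id)
    }
    truth[[ci]] <- members
  }
  for (ni in seq_len(noise_ids)) {
    k <- k + 1L
    id <- sprintf("F%03d", k)
    rows[[id]] <- data.frame(id = id, mz = 400 + ni * 17.777,
                             rtime = 2000 + ni * 100)
  }
  feats <- do.call(rbind, rows)
  X <- matrix(rep(1000, nrow(feats) * 2), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  list(table = new_feature_table(feats, X, c("s1", "s2")), truth = truth)
}

grouping_sets <- function(res) {
  lapply(res$empcpds, function(ec) sort(ec$ms1_features$feature_id))
}
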