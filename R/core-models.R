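#' @importFrom stats median sd cor prcomp hclust as.dist rnorm runif rlnorm var
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Monoisotopic mass constants (Da), CODATA/IUPAC atomic masses.
PROTON_MASS <- 1.0072765
C13_C12_DELTA <- 1.0033548

#' Construct an MS spectrum
#'
#' A centroided peak list at a given MS level. Peaks are stored sorted by
#' ascending m/z; negative intensities are rejected. For MS level >= 2 a
#' precursor m/z is mandatory.
#'
#' @param peaks two-column numeric matrix (mz, intensity) or data.frame.
#' @param ms_level integer >= 1.
#' @param precursor_mz precursor m/z in Da; required when `ms_level >= 2`.
#' @param retention_time retention time in seconds.
#' @param source_acquisition identifier of the acquisition the scan came from.
#' @return object of class `MSSpectrum`.
#' @export
new_ms_spectrum <- function(peaks, ms_level = 2L, precursor_mz = NULL,
                            retention_time = NA_real_,
                            source_acquisition = NA_character_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2) stop("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0")
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  ms_level <- as.integer(ms_level)
  if (ms_level < 1L) stop("ms_level must be >= 1")
  if (ms_level >= 2L && (is.null(precursor_mz) || is.na(precursor_mz)))
    stop("precursor_mz is required for ms_level >= 2")
  if (ms_level < 2L) precursor_mz <- NULL
  structure(list(
    peaks = peaks,
    ms_level = ms_level,
    precursor_mz = if (is.null(precursor_mz)) NULL else as.numeric(precursor_mz),
    retention_time = as.numeric(retention_time),
    source_acquisition = source_acquisition
  ), class = "MSSpectrum")
}

#' Construct a chromatographic elution peak
#'
#' @param mz m/z in Da.
#' @param rt_apex,rt_left,rt_right apex and boundary retention times (s);
#'   must satisfy `rt_left <= rt_apex <= rt_right`.
#' @param area,height integrated area and apex height (counts, > 0).
#' @param snr signal-to-noise ratio.
#' @return object of class `ElutionPeak`.
#' @export
new_elution_peak <- function(mz, rt_apex, rt_left, rt_right, area, height,
                             snr = NA_real_) {
  if (!(rt_left <= rt_apex && rt_apex <= rt_right))
    stop("require rt_left <= rt_apex <= rt_right")
  if (area <= 0 || height <= 0) stop("area and height must be > 0")
  structure(list(mz = mz, rt_apex = rt_apex, rt_left = rt_left,
                 rt_right = rt_right, area = area, height = height, snr = snr),
            class = "ElutionPeak")
}

#' Construct an annotation record
#'
#' Annotation confidence levels follow a four-tier convention in the spirit
#' of the Schymanski scheme as used here: `"1a"` = MS2 match against an
#' authentic-standard library, `"1b"` = m/z + retention-time match to an
#' authentic standard, `"2"` = MS2 match against an external library,
#' `"4"` = neutral-mass-only match.
#'
#' Level-specific evidence is enforced: `"1b"` requires retention-time
#' evidence (`rt_error_s`), `"1a"`/`"2"` require a numeric MS2 `score`, and
#' `"4"` requires a mass or formula match record (`ppm_error` or a formula
#' identifier).
#'
#' @param level one of `"1a"`, `"1b"`, `"2"`, `"4"`.
#' @param compound_name compound name.
#' @param identifiers named list mapping namespace to identifier.
#' @param score numeric score in `[0, 1]` or `NULL`.
#' @param source name of the library or standard set used.
#' @param evidence named list of free-form evidence (matched peaks, ppm
#'   error, rt error).
#' @return object of class `Annotation`.
#' @export
new_annotation <- function(level, compound_name, identifiers = list(),
                           score = NULL, source = "", evidence = list()) {
  level <- match.arg(level, c("1a", "1b", "2", "4"))
  ann <- structure(list(level = level, compound_name = compound_name,
                        identifiers = identifiers,
                        score = if (is.null(score)) NULL else as.numeric(score),
                        source = source, evidence = evidence),
                   class = "Annotation")
  err <- validate_annotation(ann)
  if (length(err)) stop("invalid annotation: ", paste(err, collapse = "; "))
  ann
}

validate_annotation <- function(ann) {
  err <- character(0)
  if (!ann$level %in% c("1a", "1b", "2", "4"))
    err <- c(err, sprintf("unknown level '%s'", ann$level))
  if (ann$level == "1b" && is.null(ann$evidence$rt_error_s))
    err <- c(err, "level 1b requires rt evidence (evidence$rt_error_s)")
  if (ann$level %in% c("1a", "2") && is.null(ann$score))
    err <- c(err, sprintf("level %s requires an MS2 score", ann$level))
  if (ann$level == "4" &&
      is.null(ann$evidence$ppm_error) && is.null(ann$identifiers$formula))
    err <- c(err, "level 4 requires a mass/formula match record")
  err
}

# Annotation ordering: level (1a, 1b, 2, 4), ties by descending score, then
# source name. Deterministic-output requirement for serialization.
annotation_order <- function(annotations) {
  if (!length(annotations)) return(integer(0))
  lvl <- match(vapply(annotations, `[[`, "", "level"), c("1a", "1b", "2", "4"))
  sc <- vapply(annotations, function(a) if (is.null(a$score)) -Inf else a$score,
               0.0)
  src <- vapply(annotations, `[[`, "", "source")
  nm <- vapply(annotations, `[[`, "", "compound_name")
  order(lvl, -sc, src, nm)
}

sort_annotations <- function(annotations) annotations[annotation_order(annotations)]

#' Construct an empirical compound
#'
#' An empirical compound groups degenerate MS1 features — isotopologues and
#' adducts of one tentative metabolite — into a single operational unit that
#' annotations from multiple tools are chained onto. Member features carry an
#' isotope tag (e.g. `"M0"`, `"13C/12C"`) and a modification (adduct) tag
#' (e.g. `"M+H[1+]"`); each (isotope, modification) grid cell may be occupied
#' at most once.
#'
#' @param interim_id provisional identifier, unique within a set.
#' @param ms1_features data.frame with columns `feature_id`, `mz`, `rtime`,
#'   `isotope`, `modification`.
#' @param charge_sign `+1` or `-1`.
#' @param neutral_formula_mass inferred neutral monoisotopic mass (Da) or `NA`.
#' @param neutral_formula molecular formula string or `NA`.
#' @param ms2_spectra list of [new_ms_spectrum()] objects attached to the
#'   compound.
#' @param annotations list of [new_annotation()] objects; stored sorted by
#'   descending confidence.
#' @return object of class `EmpiricalCompound`.
#' @export
new_empirical_compound <- function(interim_id, ms1_features,
                                   charge_sign = 1L,
                                   neutral_formula_mass = NA_real_,
                                   neutral_formula = NA_character_,
                                   ms2_spectra = list(),
                                   annotations = list()) {
  ms1_features <- as.data.frame(ms1_features, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rtime", "isotope", "modification")
  miss <- setdiff(need, names(ms1_features))
  if (length(miss))
    stop("ms1_features missing columns: ", paste(miss, collapse = ", "))
  ec <- structure(list(
    interim_id = as.character(interim_id),
    neutral_formula_mass = as.numeric(neutral_formula_mass),
    neutral_formula = as.character(neutral_formula),
    charge_sign = as.integer(charge_sign),
    ms1_features = ms1_features[, need, drop = FALSE],
    ms2_spectra = ms2_spectra,
    annotations = sort_annotations(annotations)
  ), class = "EmpiricalCompound")
  err <- validate_empirical_compound(ec)
  if (length(err))
    stop(sprintf("invalid empirical compound '%s': %s", interim_id,
                 paste(err, collapse = "; ")))
  ec
}

validate_empirical_compound <- function(ec) {
  err <- character(0)
  if (!ec$charge_sign %in% c(1L, -1L)) err <- c(err, "charge_sign must be +1 or -1")
  cells <- paste(ec$ms1_features$isotope, ec$ms1_features$modification, sep = "|")
  if (anyDuplicated(cells))
    err <- c(err, sprintf("duplicate (isotope, modification) pair: %s",
                          paste(unique(cells[duplicated(cells)]), collapse = ", ")))
  for (a in ec$annotations) err <- c(err, validate_annotation(a))
  err
}

#' Construct an acquisition record
#'
#' An acquisition is one instance of a data file produced by analyzing a
#' sample (LC-MS injection).
#'
#' @param name sample/acquisition name, unique in an experiment.
#' @param filepath path to the raw or converted data file.
#' @param sample_type one of `"study"`, `"blank"`, `"pool"`, `"standard"`.
#' @param batch batch label.
#' @param metadata arbitrary named list of additional attributes.
#' @return object of class `Acquisition`.
#' @export
new_acquisition <- function(name, filepath = NA_character_,
                            sample_type = "study", batch = "1",
                            metadata = list()) {
  sample_type <- match.arg(sample_type, c("study", "blank", "pool", "standard"))
  structure(list(name = as.character(name), filepath = as.character(filepath),
                 sample_type = sample_type, batch = as.character(batch),
                 metadata = metadata),
            class = "Acquisition")
}

#' Construct a feature table
#'
#' The central QC container: a features-by-acquisitions intensity matrix with
#' per-feature m/z and retention-time metadata and a provenance tag naming
#' the processing stage that produced it. Missing intensities are stored as
#' zeros; imputation is an explicit, separate step.
#'
#' @param features data.frame with columns `id`, `mz`, `rtime` (one row per
#'   feature; `id` unique, `mz > 0`, `rtime >= 0`). Extra quality-metric
#'   columns (e.g. `snr`) are carried along.
#' @param intensities numeric matrix, rows matching `features$id`, columns
#'   named by acquisition ids; all values >= 0.
#' @param acquisitions ordered character vector of acquisition ids; defaults
#'   to `colnames(intensities)`.
#' @param provenance_tag stage label, e.g. `"ingested"` or `"normalized"`.
#' @return object of class `FeatureTable`.
#' @export
new_feature_table <- function(features, intensities,
                              acquisitions = colnames(intensities),
                              provenance_tag = "ingested") {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- features$id
  ft <- structure(list(features = features, intensities = intensities,
                       acquisitions = as.character(acquisitions),
                       provenance_tag = provenance_tag),
                  class = "FeatureTable")
  err <- validate_feature_table(ft)
  if (length(err))
    stop("invalid feature table: ",
         paste(vapply(err, `[[`, "", "message"), collapse = "; "))
  ft
}

#' Validate a feature table
#'
#' Reporting operation: returns an empty list iff all invariants hold,
#' otherwise one violation record per broken rule, each naming the offending
#' feature or acquisition.
#'
#' @param table a `FeatureTable` (or a structurally similar list, for
#'   checking objects built by hand).
#' @return list of violation records, each a list with `rule`, `subject`,
#'   `message`.
#' @export
validate_feature_table <- function(table) {
  v <- list()
  viol <- function(rule, subject, message)
    list(rule = rule, subject = subject, message = message)
  ids <- table$features$id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v[[length(v) + 1L]] <- viol("duplicate id", paste(dup, collapse = ","),
      sprintf("duplicate feature id(s): %s", paste(dup, collapse = ", ")))
  if (any(bad <- !is.finite(table$features$mz) | table$features$mz <= 0))
    v[[length(v) + 1L]] <- viol("mz > 0", paste(ids[bad], collapse = ","),
      sprintf("non-positive m/z for: %s", paste(ids[bad], collapse = ", ")))
  if (any(bad <- !is.finite(table$features$rtime) | table$features$rtime < 0))
    v[[length(v) + 1L]] <- viol("rtime >= 0", paste(ids[bad], collapse = ","),
      sprintf("negative rtime for: %s", paste(ids[bad], collapse = ", ")))
  orphan <- setdiff(colnames(table$intensities), table$acquisitions)
  if (length(orphan))
    v[[length(v) + 1L]] <- viol("undeclared acquisition",
      paste(orphan, collapse = ","),
      sprintf("intensity column(s) not in acquisitions: %s",
              paste(orphan, collapse = ", ")))
  if (nrow(table$intensities) != nrow(table$features))
    v[[length(v) + 1L]] <- viol("dimension", "intensities",
      "intensity row count differs from feature count")
  if (any(table$intensities < 0))
    v[[length(v) + 1L]] <- viol("intensity >= 0",
      paste(unique(ids[which(rowSums(table$intensities < 0) > 0)]), collapse = ","),
      "negative intensities present")
  v
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable [%s]: %d features x %d acquisitions\n",
              x$provenance_tag, nrow(x$features), length(x$acquisitions)))
  invisible(x)
}

#' @export
print.EmpiricalCompound <- function(x, ...) {
  cat(sprintf("EmpiricalCompound %s: %d features, %d MS2 spectra, %d annotations",
              x$interim_id, nrow(x$ms1_features), length(x$ms2_spectra),
              length(x$annotations)))
  if (is.finite(x$neutral_formula_mass))
    cat(sprintf(", neutral mass %.6f", x$neutral_formula_mass))
  cat("\n")
  invisible(x)
}

# ---- metabolic model carrier types (data only; no flux computation) --------

#' Metabolic model carrier types
#'
#' Plain data containers for genome-scale metabolic model components
#' (compounds, reactions, enzymes, genes, pathways, and a network of
#' reactions). These are reference-data carriers used by annotation; no
#' constraint-based computation is performed on them.
#'
#' @param id identifier.
#' @param name human-readable name.
#' @param formula molecular formula.
#' @param neutral_mono_mass neutral monoisotopic mass (Da).
#' @return the respective typed list.
#' @export
new_compound <- function(id, name = id, formula = NA_character_,
                         neutral_mono_mass = NA_real_) {
  structure(list(id = id, name = name, formula = formula,
                 neutral_mono_mass = as.numeric(neutral_mono_mass)),
            class = "mm_compound")
}

#' @rdname new_compound
#' @param substrates,products character vectors of compound ids.
#' @param enzymes character vector of enzyme ids.
#' @export
new_reaction <- function(id, substrates, products, enzymes = character(0)) {
  structure(list(id = id, substrates = substrates, products = products,
                 enzymes = enzymes), class = "mm_reaction")
}

#' @rdname new_compound
#' @param genes character vector of gene ids.
#' @export
new_enzyme <- function(id, genes = character(0)) {
  structure(list(id = id, genes = genes), class = "mm_enzyme")
}

#' @rdname new_compound
#' @param reactions character vector of reaction ids.
#' @export
new_pathway <- function(id, name = id, reactions = character(0)) {
  structure(list(id = id, name = name, reactions = reactions),
            class = "mm_pathway")
}

#' @rdname new_compound
#' @param compounds list of `mm_compound`.
#' @param reaction_list list of `mm_reaction`.
#' @param pathways list of `mm_pathway`.
#' @export
new_metabolic_network <- function(compounds = list(), reaction_list = list(),
                                  pathways = list()) {
  net <- structure(list(compounds = compounds, reactions = reaction_list,
                        pathways = pathways), class = "mm_network")
  cids <- vapply(compounds, `[[`, "", "id")
  rids <- vapply(reaction_list, `[[`, "", "id")
  for (r in reaction_list) {
    bad <- setdiff(c(r$substrates, r$products), cids)
    if (length(bad))
      stop(sprintf("reaction %s references undeclared compound(s): %s",
                   r$id, paste(bad, collapse = ", ")))
  }
  for (p in pathways) {
    bad <- setdiff(p$reactions, rids)
    if (length(bad))
      stop(sprintf("pathway %s references undeclared reaction(s): %s",
                   p$id, paste(bad, collapse = ", ")))
  }
  net
}
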