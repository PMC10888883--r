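# Empirical-compound JSON: the chaining format. Key order is fixed so that
# serialization is byte-stable for equal inputs; the schema ships in
# inst/extdata/empirical_compound.schema.json.

empcpd_to_list <- function(ec) {
  feats <- ec$ms1_features
  ms1 <- lapply(seq_len(nrow(feats)), function(i) list(
    feature_id = feats$feature_id[i],
    mz = feats$mz[i],
    rtime = feats$rtime[i],
    isotope = feats$isotope[i],
    modification = feats$modification[i]
  ))
  ms2 <- lapply(ec$ms2_spectra, function(sp) list(
    precursor_mz = sp$precursor_mz,
    retention_time = sp$retention_time,
    source_acquisition = sp$source_acquisition,
    peaks = unname(apply(sp$peaks, 1, function(r) list(r[[1]], r[[2]]),
                         simplify = FALSE))
  ))
  anns <- lapply(ec$annotations, function(a) list(
    level = a$level,
    compound_name = a$compound_name,
    identifiers = a$identifiers,
    score = if (is.null(a$score)) NA else a$score,
    source = a$source,
    evidence = a$evidence
  ))
  list(
    interim_id = ec$interim_id,
    neutral_formula_mass = ec$neutral_formula_mass,
    neutral_formula = ec$neutral_formula,
    charge_sign = ec$charge_sign,
    MS1_pseudo_Spectra = ms1,
    MS2_Spectra = ms2,
    annotations = anns
  )
}

#' Serialize a set of empirical compounds to JSON
#'
#' Produces a UTF-8 JSON array, one object per empirical compound, with a
#' fixed key order so equal inputs serialize to identical bytes. This format
#' is the hand-off point between pipeline stages and external annotation
#' tools; [parse_empcpd_set()] is its exact inverse.
#'
#' @param empcpds list of `EmpiricalCompound` objects.
#' @param pretty pretty-print the JSON.
#' @return a single JSON string.
#' @export
serialize_empcpd_set <- function(empcpds, pretty = FALSE) {
  for (ec in empcpds) {
    err <- validate_empirical_compound(ec)
    if (length(err))
      stop(sprintf("invalid empirical compound '%s': %s", ec$interim_id,
                   paste(err, collapse = "; ")))
  }
  body <- lapply(empcpds, empcpd_to_list)
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, na = "null",
                                null = "null", digits = NA, pretty = pretty))
}

#' Parse a set of empirical compounds from JSON
#'
#' Inverse of [serialize_empcpd_set()]. All type invariants are re-validated
#' on parse; violations raise an error naming the offending `interim_id` and
#' field.
#'
#' @param text JSON string (or path to a JSON file).
#' @return list of `EmpiricalCompound` objects.
#' @export
parse_empcpd_set <- function(text) {
  if (length(text) == 1 && !startsWith(trimws(text), "[") && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  raw <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  lapply(raw, function(x) {
    nullable_num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    nullable_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
    ms1 <- if (length(x$MS1_pseudo_Spectra)) {
      do.call(rbind, lapply(x$MS1_pseudo_Spectra, function(f)
        data.frame(feature_id = f$feature_id, mz = as.numeric(f$mz),
                   rtime = as.numeric(f$rtime), isotope = f$isotope,
                   modification = f$modification, stringsAsFactors = FALSE)))
    } else {
      data.frame(feature_id = character(0), mz = numeric(0), rtime = numeric(0),
                 isotope = character(0), modification = character(0))
    }
    ms2 <- lapply(x$MS2_Spectra, function(sp) {
      pk <- if (length(sp$peaks)) {
        do.call(rbind, lapply(sp$peaks, function(p) c(p[[1]], p[[2]])))
      } else matrix(numeric(0), ncol = 2)
      new_ms_spectrum(pk, ms_level = 2L, precursor_mz = sp$precursor_mz,
                      retention_time = nullable_num(sp$retention_time),
                      source_acquisition = nullable_chr(sp$source_acquisition))
    })
    anns <- lapply(x$annotations, function(a)
      new_annotation(a$level, a$compound_name,
                     identifiers = a$identifiers,
                     score = if (is.null(a$score)) NULL else a$score,
                     source = a$source, evidence = a$evidence))
    new_empirical_compound(
      interim_id = x$interim_id,
      ms1_features = ms1,
      charge_sign = x$charge_sign,
      neutral_formula_mass = nullable_num(x$neutral_formula_mass),
      neutral_formula = nullable_chr(x$neutral_formula),
      ms2_spectra = ms2,
      annotations = anns
    )
  })
}

#' Write/read an empirical compound set JSON file
#'
#' @param empcpds list of `EmpiricalCompound`.
#' @param path file path.
#' @return `write_empcpd_set` returns `path` invisibly; `read_empcpd_set`
#'   returns the parsed list.
#' @export
write_empcpd_set <- function(empcpds, path) {
  writeLines(serialize_empcpd_set(empcpds), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_empcpd_set
#' @export
read_empcpd_set <- function(path) {
  parse_empcpd_set(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
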