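# Minimal mzML support: extraction of centroided MS2 spectra (precursor m/z,
# retention time normalized to seconds, peak lists) from standard mzML, and a
# small writer used by the synthetic-fixtures module. Binary data arrays are
# base64-encoded IEEE floats, optionally zlib-compressed, per the PSI mzML
# CV (MS:1000523 64-bit, MS:1000521 32-bit, MS:1000574 zlib).

decode_binary_array <- function(b64, precision_bits, zlib) {
  if (!nzchar(b64)) return(numeric(0))
  raw <- jsonlite::base64_dec(b64)
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", size = precision_bits / 8,
          n = length(raw) / (precision_bits / 8))
}

encode_binary_array <- function(x, precision_bits = 64, zlib = FALSE) {
  raw <- writeBin(as.double(x), raw(), size = precision_bits / 8)
  if (zlib) raw <- memCompress(raw, type = "gzip")
  gsub("\n", "", jsonlite::base64_enc(raw))
}

cv_has <- function(node, accession) {
  length(xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))) > 0 &&
    !inherits(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession)), "xml_missing")
}

cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                          accession))
  if (inherits(p, "xml_missing")) return(NULL)
  xml2::xml_attr(p, "value")
}

#' Extract MS2 spectra from an mzML file
#'
#' Reads centroided MS2 scans: precursor m/z, retention time (normalized to
#' seconds regardless of the unit the file uses), and the peak list. MS1
#' scans are ignored; profile-mode MS2 scans and MS2 scans lacking a
#' precursor are skipped, with the skip count reported via the `"n_skipped"`
#' attribute and a message.
#'
#' @param path mzML file path.
#' @return list of [new_ms_spectrum()] objects (ms_level = 2), attribute
#'   `"n_skipped"` counting skipped MS2 scans.
#' @export
extract_ms2_from_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  acq <- tools::file_path_sans_ext(basename(path))
  out <- list()
  n_skipped <- 0L
  for (sp in spectra) {
    lvl <- cv_value(sp, "MS:1000511")
    if (is.null(lvl) || as.integer(lvl) < 2L) next
    if (cv_has(sp, "MS:1000128")) {            # profile mode
      n_skipped <- n_skipped + 1L
      next
    }
    ion <- xml2::xml_find_first(sp, ".//precursorList//selectedIon")
    prec <- if (inherits(ion, "xml_missing")) NULL
            else cv_value(ion, "MS:1000744")
    if (is.null(prec)) {
      n_skipped <- n_skipped + 1L
      next
    }
    scan <- xml2::xml_find_first(sp, ".//scanList/scan/cvParam[@accession='MS:1000016']")
    rt <- NA_real_
    if (!inherits(scan, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(scan, "value"))
      unit <- xml2::xml_attr(scan, "unitName")
      if (!is.na(unit) && grepl("min", unit, ignore.case = TRUE))
        rt <- rt * 60
    }
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- inten <- numeric(0)
    for (arr in arrays) {
      bits <- if (cv_has(arr, "MS:1000521")) 32L else 64L
      zlib <- cv_has(arr, "MS:1000574")
      b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
      vals <- decode_binary_array(b64, bits, zlib)
      if (cv_has(arr, "MS:1000514")) mz <- vals
      if (cv_has(arr, "MS:1000515")) inten <- vals
    }
    out[[length(out) + 1L]] <- new_ms_spectrum(
      cbind(mz, inten), ms_level = 2L, precursor_mz = as.numeric(prec),
      retention_time = rt, source_acquisition = acq)
  }
  if (n_skipped > 0)
    message(sprintf("extract_ms2_from_mzml: skipped %d MS2 scan(s) (profile mode or missing precursor)",
                    n_skipped))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a minimal synthetic mzML file
#'
#' Fixture writer for tests and the synthetic-data module: emits a valid
#' (minimal) mzML document containing the given spectra. Not a general mzML
#' exporter — indexing, chromatograms and instrument metadata are omitted.
#'
#' @param spectra list of `MSSpectrum` objects (MS1 and/or MS2).
#' @param path output path.
#' @param rt_unit `"second"` or `"minute"`: unit used to *encode* retention
#'   times in the file (values are converted from seconds accordingly).
#' @param zlib compress binary arrays with zlib.
#' @param profile_idx integer indices of spectra to mark as profile mode
#'   (used to exercise the reader's skip path).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path, rt_unit = c("second", "minute"),
                       zlib = FALSE, profile_idx = integer(0)) {
  rt_unit <- match.arg(rt_unit)
  compression_cv <- if (zlib) {
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  }
  entry <- function(i, sp) {
    rt <- sp$retention_time
    rt_enc <- if (rt_unit == "minute") rt / 60 else rt
    mode_cv <- if (i %in% profile_idx) {
      '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>'
    } else {
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>'
    }
    prec <- if (sp$ms_level >= 2L && !is.null(sp$precursor_mz)) sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.12g"/></selectedIon></selectedIonList></precursor></precursorList>',
      sp$precursor_mz) else ""
    arr <- function(vals, acc, nm) sprintf(paste0(
      '<binaryDataArray encodedLength="0">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>%s',
      '<cvParam cvRef="MS" accession="%s" name="%s"/>',
      '<binary>%s</binary></binaryDataArray>'),
      compression_cv, acc, nm, encode_binary_array(vals, 64, zlib))
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>%s',
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.12g" unitName="%s"/></scan></scanList>',
      '%s<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
      i - 1L, i, nrow(sp$peaks), sp$ms_level, mode_cv, rt_enc, rt_unit, prec,
      arr(sp$peaks[, "mz"], "MS:1000514", "m/z array"),
      arr(sp$peaks[, "intensity"], "MS:1000515", "intensity array"))
  }
  body <- vapply(seq_along(spectra), function(i) entry(i, spectra[[i]]), "")
  doc <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    sprintf('<run id="synthetic"><spectrumList count="%d">', length(spectra)),
    body,
    '</spectrumList></run></mzML>')
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}
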