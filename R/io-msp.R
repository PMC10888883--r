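# MSP spectral library reader/writer. MSP is the plain-text library format
# MoNA distributes: "Name:" starts an entry, "Num Peaks: N" is followed by N
# whitespace-separated (mz, intensity) pairs, possibly several per line.

#' Construct a reference spectrum
#'
#' A library MS2 spectrum with compound identity, as parsed from an MSP
#' library or built by the synthetic generator.
#'
#' @param compound_name compound name.
#' @param precursor_mz precursor m/z (Da); `NA` for entries lacking one
#'   (retained but not indexable by precursor).
#' @param peaks two-column (mz, intensity) matrix; stored sorted by mz.
#' @param source_library library name.
#' @param is_authentic_standard whether the entry comes from an in-house
#'   authentic-standard library (controls level 1a vs 2 on match).
#' @param formula optional molecular formula.
#' @return object of class `RefSpectrum`.
#' @export
new_ref_spectrum <- function(compound_name, precursor_mz, peaks,
                             source_library = "library",
                             is_authentic_standard = FALSE,
                             formula = NA_character_) {
  peaks <- as.matrix(peaks)
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(peaks[, "intensity"] < 0)) stop("intensities must be >= 0")
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  structure(list(compound_name = compound_name,
                 precursor_mz = as.numeric(precursor_mz),
                 peaks = peaks, source_library = source_library,
                 is_authentic_standard = isTRUE(is_authentic_standard),
                 formula = formula),
            class = "RefSpectrum")
}

#' Read an MSP spectral library
#'
#' Entries lacking a precursor m/z are retained with `precursor_mz = NA`
#' (flagged non-indexable). An entry whose "Num Peaks" count disagrees with
#' the number of peak pairs actually present is skipped with a warning; the
#' remainder of the file is still parsed.
#'
#' @param path MSP file path.
#' @param is_authentic_standard mark all entries as authentic standards.
#' @return list of [new_ref_spectrum()] objects; attribute `"n_skipped"`
#'   counts skipped entries.
#' @export
read_msp_library <- function(path, is_authentic_standard = FALSE) {
  lines <- readLines(path, warn = FALSE)
  src <- tools::file_path_sans_ext(basename(path))
  entries <- list()
  n_skipped <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i], ignore.case = TRUE)) { i <- i + 1L; next }
    name <- trimws(sub("^Name:", "", lines[i], ignore.case = TRUE))
    precursor <- NA_real_; formula <- NA_character_; num_peaks <- NA_integer_
    i <- i + 1L
    while (i <= n && !grepl("^Num ?Peaks:", lines[i], ignore.case = TRUE) &&
           !grepl("^Name:", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^(PrecursorMZ|Precursor_MZ|PRECURSORMZ):", ln, ignore.case = TRUE))
        precursor <- suppressWarnings(as.numeric(trimws(sub("^[^:]+:", "", ln))))
      if (grepl("^Formula:", ln, ignore.case = TRUE))
        formula <- trimws(sub("^[^:]+:", "", ln))
      i <- i + 1L
    }
    if (i > n || !grepl("^Num ?Peaks:", lines[i], ignore.case = TRUE)) {
      warning(sprintf("MSP entry '%s' has no Num Peaks field; skipped", name))
      n_skipped <- n_skipped + 1L
      next
    }
    num_peaks <- as.integer(trimws(sub("^[^:]+:", "", lines[i])))
    i <- i + 1L
    vals <- numeric(0)
    while (i <= n && nzchar(trimws(lines[i])) &&
           !grepl("^Name:", lines[i], ignore.case = TRUE)) {
      toks <- strsplit(trimws(lines[i]), "[[:space:];]+")[[1]]
      vals <- c(vals, suppressWarnings(as.numeric(toks)))
      i <- i + 1L
    }
    if (anyNA(vals) || length(vals) %% 2 != 0 || length(vals) / 2 != num_peaks) {
      warning(sprintf(
        "MSP entry '%s': Num Peaks (%d) disagrees with %s peak pairs; skipped",
        name, num_peaks, format(length(vals) / 2)))
      n_skipped <- n_skipped + 1L
      next
    }
    peaks <- matrix(vals, ncol = 2, byrow = TRUE)
    entries[[length(entries) + 1L]] <- new_ref_spectrum(
      name, precursor, peaks, source_library = src,
      is_authentic_standard = is_authentic_standard, formula = formula)
  }
  attr(entries, "n_skipped") <- n_skipped
  entries
}

#' Write a list of reference spectra as an MSP library
#'
#' @param refs list of `RefSpectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp_library <- function(refs, path) {
  out <- character(0)
  for (r in refs) {
    out <- c(out, paste0("Name: ", r$compound_name))
    if (is.finite(r$precursor_mz))
      out <- c(out, paste0("PrecursorMZ: ", sprintf("%.12g", r$precursor_mz)))
    if (!is.na(r$formula)) out <- c(out, paste0("Formula: ", r$formula))
    out <- c(out, paste0("Num Peaks: ", nrow(r$peaks)))
    out <- c(out, sprintf("%.12g %.12g", r$peaks[, 1], r$peaks[, 2]))
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
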