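# Tabular I/O: feature table TSV (asari-style or generic dialect), sample
# metadata CSV, and the three-table export. All writers format numbers with
# %.12g so round-trips agree to well below 1e-9 relative and re-exports are
# byte-identical.

FMT_NUM <- function(x) {
  out <- sprintf("%.12g", x)
  out[!is.finite(x)] <- ""
  out
}

# Leading metadata columns of an asari-style table; anything after these is a
# sample intensity column.
ASARI_META_COLS <- c("id_number", "mz", "rtime", "rtime_left_base",
                     "rtime_right_base", "parent_masstrack_id", "peak_area",
                     "cSelectivity", "goodness_fitting", "snr",
                     "detection_counts")

#' Read an aligned feature table from TSV
#'
#' Reads a tab-separated feature table with one row per aligned feature. Two
#' dialects are supported: `"asari"` (fixed leading metadata columns
#' `id_number`, `mz`, `rtime`, optional quality columns, then one numeric
#' column per sample) and `"generic"` (user-named id/mz/rtime columns; every
#' remaining column is a sample).
#'
#' Missing intensity cells are read as 0 (imputation is an explicit QC step);
#' non-numeric intensity cells are an error, not silently coerced.
#'
#' @param path TSV file path.
#' @param dialect `"asari"` or `"generic"`.
#' @param id_col,mz_col,rtime_col column names for the generic dialect.
#' @return a [new_feature_table()] object tagged `"ingested"`.
#' @export
read_feature_table <- function(path, dialect = c("asari", "generic"),
                               id_col = "id", mz_col = "mz",
                               rtime_col = "rtime") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty feature table: ", path)
  if (dialect == "asari") {
    id_col <- "id_number"; mz_col <- "mz"; rtime_col <- "rtime"
  }
  need <- c(id_col, mz_col, rtime_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta_cols <- if (dialect == "asari") intersect(ASARI_META_COLS, names(df))
               else need
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols)) stop("no sample intensity columns found")
  num <- function(col, what) {
    x <- df[[col]]
    x[is.na(x) | x == ""] <- if (what == "intensity") "0" else NA
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric %s value in column '%s', row(s) %s", what,
                   col, paste(head(bad, 5), collapse = ", ")))
    v
  }
  intens <- vapply(sample_cols, num, numeric(nrow(df)), what = "intensity")
  intens <- matrix(intens, nrow = nrow(df),
                   dimnames = list(ids, sample_cols))
  features <- data.frame(id = ids, mz = num(mz_col, "mz"),
                         rtime = num(rtime_col, "rtime"),
                         stringsAsFactors = FALSE)
  for (qc in intersect(c("snr", "goodness_fitting"), meta_cols))
    features[[qc]] <- suppressWarnings(as.numeric(df[[qc]]))
  new_feature_table(features, intens, sample_cols, provenance_tag = "ingested")
}

#' Write a feature table to TSV
#'
#' Generic-dialect writer: columns `id`, `mz`, `rtime`, then one column per
#' acquisition. Deterministic formatting so repeated exports are
#' byte-identical.
#'
#' @param table a `FeatureTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  hdr <- c("id", "mz", "rtime", table$acquisitions)
  rows <- vapply(seq_len(nrow(table$features)), function(i) {
    paste(c(table$features$id[i], FMT_NUM(table$features$mz[i]),
            FMT_NUM(table$features$rtime[i]),
            FMT_NUM(table$intensities[i, table$acquisitions])),
          collapse = "\t")
  }, "")
  writeLines(c(paste(hdr, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read sample metadata CSV
#'
#' Minimally maps sample names to acquisition file paths; optional `batch`
#' and `sample_type` columns (defaults `"1"` and `"study"`). Column names are
#' matched case-insensitively: the sample column may be called `sample`,
#' `sample_name` or `name`; the path column `filepath`, `file` or `path`.
#'
#' @param path CSV file path.
#' @return list of [new_acquisition()] objects.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty sample metadata file: ", path)
  find_col <- function(cands) {
    hit <- which(tolower(names(df)) %in% cands)
    if (length(hit)) names(df)[hit[1]] else NULL
  }
  name_col <- find_col(c("sample", "sample_name", "name"))
  path_col <- find_col(c("filepath", "file", "path", "file_path"))
  if (is.null(name_col))
    stop("sample metadata needs a sample-name column (sample/sample_name/name)")
  if (is.null(path_col))
    stop("sample metadata needs a filepath column (filepath/file/path)")
  type_col <- find_col(c("sample_type", "type"))
  batch_col <- find_col(c("batch"))
  nms <- as.character(df[[name_col]])
  if (anyDuplicated(nms))
    stop("duplicate sample name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  extra_cols <- setdiff(names(df), c(name_col, path_col, type_col, batch_col))
  lapply(seq_len(nrow(df)), function(i) {
    meta <- as.list(df[i, extra_cols, drop = FALSE])
    new_acquisition(
      name = nms[i],
      filepath = as.character(df[[path_col]][i]),
      sample_type = if (is.null(type_col)) "study"
                    else as.character(df[[type_col]][i]),
      batch = if (is.null(batch_col)) "1" else as.character(df[[batch_col]][i]),
      metadata = meta)
  })
}

#' Write sample metadata CSV for a list of acquisitions
#'
#' @param acquisitions list of `Acquisition`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(acquisitions, path) {
  extra <- sort(unique(unlist(lapply(acquisitions, function(a) names(a$metadata)))))
  hdr <- c("sample", "filepath", "sample_type", "batch", extra)
  rows <- vapply(acquisitions, function(a) {
    ex <- vapply(extra, function(k) {
      v <- a$metadata[[k]]
      if (is.null(v)) "" else as.character(v)
    }, "")
    paste(c(a$name, a$filepath, a$sample_type, a$batch, ex), collapse = ",")
  }, "")
  writeLines(c(paste(hdr, collapse = ","), rows), path, useBytes = TRUE)
  invisible(path)
}

# ---- three-table export ----------------------------------------------------

#' Export the standardized three-table output
#'
#' Writes the pipeline's final output convention: (1) a feature table TSV
#' (id, m/z, retention time, per-acquisition intensities); (2) an annotation
#' table TSV with one row per (feature, annotation) pair — a feature carrying
#' several annotations appears on several rows, so multiple annotations are
#' represented without loss; (3) a sample table CSV of acquisition- and
#' experiment-level metadata. Referential integrity (annotation feature ids
#' subset of feature table ids; acquisition columns present as sample rows)
#' is checked programmatically before returning.
#'
#' @param experiment an [assemble_experiment()] object.
#' @param table_name name of a stored feature table in the experiment.
#' @param empcpd_set_name name of a stored empirical compound set, or `NULL`
#'   for an annotation table with header only.
#' @param out_dir output directory (created if needed).
#' @return list with `feature_table_path`, `annotation_table_path`,
#'   `sample_table_path`.
#' @export
export_three_tables <- function(experiment, table_name, empcpd_set_name,
                                out_dir) {
  table <- experiment_get_table(experiment, table_name)
  empcpds <- if (is.null(empcpd_set_name)) list()
             else experiment_get_empcpds(experiment, empcpd_set_name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft_path <- file.path(out_dir, "feature_table.tsv")
  an_path <- file.path(out_dir, "annotation_table.tsv")
  sm_path <- file.path(out_dir, "sample_table.csv")
  write_feature_table(table, ft_path)

  ann_hdr <- c("feature_id", "empcpd_id", "isotope", "modification",
               "neutral_formula_mass", "level", "compound_name", "score",
               "source", "ppm_error", "rt_error_s", "identifiers")
  present <- table$features$id
  rows <- character(0)
  for (ec in empcpds) {
    members <- ec$ms1_features[ec$ms1_features$feature_id %in% present, ,
                               drop = FALSE]
    if (!nrow(members) || !length(ec$annotations)) next
    for (i in seq_len(nrow(members))) {
      for (a in ec$annotations) {
        ev_num <- function(k) {
          v <- a$evidence[[k]]
          if (is.null(v)) "" else FMT_NUM(as.numeric(v))
        }
        rows <- c(rows, paste(c(
          members$feature_id[i], ec$interim_id, members$isotope[i],
          members$modification[i],
          if (is.finite(ec$neutral_formula_mass))
            FMT_NUM(ec$neutral_formula_mass) else "",
          a$level, a$compound_name,
          if (is.null(a$score)) "" else FMT_NUM(a$score),
          a$source, ev_num("ppm_error"), ev_num("rt_error_s"),
          as.character(jsonlite::toJSON(a$identifiers, auto_unbox = TRUE))
        ), collapse = "\t"))
      }
    }
  }
  writeLines(c(paste(ann_hdr, collapse = "\t"), rows), an_path,
             useBytes = TRUE)

  acqs <- experiment$acquisitions[
    vapply(experiment$acquisitions, `[[`, "", "name") %in% table$acquisitions]
  write_sample_metadata(acqs, sm_path)

  out <- list(feature_table_path = ft_path, annotation_table_path = an_path,
              sample_table_path = sm_path)
  check_three_table_integrity(out)
  out
}

#' Verify referential integrity of a three-table export
#'
#' @param export list as returned by [export_three_tables()].
#' @return `TRUE` invisibly; errors on any violation.
#' @export
check_three_table_integrity <- function(export) {
  ft <- utils::read.delim(export$feature_table_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  an <- utils::read.delim(export$annotation_table_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sm <- utils::read.csv(export$sample_table_path, stringsAsFactors = FALSE)
  if (nrow(an)) {
    orphan <- setdiff(as.character(an$feature_id), as.character(ft$id))
    if (length(orphan))
      stop("annotation table references unknown feature id(s): ",
           paste(orphan, collapse = ", "))
  }
  acq_cols <- setdiff(names(ft), c("id", "mz", "rtime"))
  missing <- setdiff(acq_cols, as.character(sm$sample))
  if (length(missing))
    stop("feature table acquisition column(s) missing from sample table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
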