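# The on-disk experiment workspace: a directory with a JSON manifest binding
# acquisitions, stored feature tables, stored empirical-compound sets, and
# an append-only command log. Stored intermediates are plain text (TSV/JSON)
# and are re-read by name in later steps, so an analysis is a chain of named
# transforms over the workspace.

manifest_path <- function(root_dir) file.path(root_dir, "manifest.json")

#' Assemble an experiment from sample metadata
#'
#' Every analysis starts here: reads the metadata CSV, registers the
#' acquisitions, creates the experiment directory with its manifest, and
#' initializes the command log.
#'
#' @param metadata_csv path to the sample metadata CSV
#'   ([read_sample_metadata()]).
#' @param out_dir experiment directory to create.
#' @param overwrite allow reuse of an existing non-empty directory.
#' @return object of class `Experiment`.
#' @export
assemble_experiment <- function(metadata_csv, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0 &&
      !overwrite)
    stop("directory exists and is non-empty: ", out_dir,
         " (use overwrite = TRUE)")
  acqs <- read_sample_metadata(metadata_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "empcpds"), showWarnings = FALSE)
  exp <- structure(list(root_dir = normalizePath(out_dir),
                        acquisitions = acqs,
                        feature_tables = list(),
                        empcpd_sets = list(),
                        command_log = list()),
                   class = "Experiment")
  exp <- log_command(exp, "assemble",
                     list(metadata_csv = metadata_csv),
                     inputs = character(0), outputs = character(0))
  save_experiment(exp)
}

#' Append a command record to the experiment log
#'
#' The log is append-only; replaying the recorded sequence on the same
#' inputs reproduces the same outputs.
#'
#' @param exp an `Experiment`.
#' @param command command name.
#' @param parameters named list of parameters.
#' @param inputs,outputs names of tables/sets read and written.
#' @return the updated `Experiment` (not yet saved).
#' @export
log_command <- function(exp, command, parameters = list(),
                        inputs = character(0), outputs = character(0)) {
  exp$command_log[[length(exp$command_log) + 1L]] <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    parameters = parameters,
    inputs = as.character(inputs),
    outputs = as.character(outputs))
  exp
}

#' Save / load the experiment manifest
#'
#' @param exp an `Experiment`.
#' @return `save_experiment` returns `exp` invisibly; `load_experiment`
#'   returns the `Experiment`.
#' @export
save_experiment <- function(exp) {
  body <- list(
    acquisitions = lapply(exp$acquisitions, function(a)
      list(name = a$name, filepath = a$filepath, sample_type = a$sample_type,
           batch = a$batch, metadata = a$metadata)),
    feature_tables = exp$feature_tables,
    empcpd_sets = exp$empcpd_sets,
    command_log = exp$command_log)
  writeLines(as.character(jsonlite::toJSON(body, auto_unbox = TRUE,
                                           null = "null", digits = NA,
                                           pretty = TRUE)),
             manifest_path(exp$root_dir), useBytes = TRUE)
  invisible(exp)
}

#' @rdname save_experiment
#' @param root_dir experiment directory.
#' @export
load_experiment <- function(root_dir) {
  mp <- manifest_path(root_dir)
  if (!file.exists(mp)) stop("no manifest found in ", root_dir)
  body <- jsonlite::fromJSON(mp, simplifyVector = FALSE)
  structure(list(
    root_dir = normalizePath(root_dir),
    acquisitions = lapply(body$acquisitions, function(a)
      new_acquisition(a$name,
                      filepath = if (is.null(a$filepath)) NA_character_
                                 else a$filepath,
                      sample_type = a$sample_type, batch = a$batch,
                      metadata = a$metadata)),
    feature_tables = body$feature_tables,
    empcpd_sets = body$empcpd_sets,
    command_log = body$command_log), class = "Experiment")
}

#' Store and retrieve named feature tables and empirical-compound sets
#'
#' Tables and sets are stored under the experiment directory by name
#' (copy-on-write: storing under an existing name is an error, so no step
#' can mutate a predecessor's output).
#'
#' @param exp an `Experiment`.
#' @param table a `FeatureTable`.
#' @param name storage name.
#' @return the updated/loaded object.
#' @export
experiment_store_table <- function(exp, table, name) {
  if (name %in% names(exp$feature_tables))
    stop("table name already in use: ", name)
  rel <- file.path("tables", paste0(name, ".tsv"))
  write_feature_table(table, file.path(exp$root_dir, rel))
  exp$feature_tables[[name]] <- rel
  save_experiment(exp)
}

#' @rdname experiment_store_table
#' @export
experiment_get_table <- function(exp, name) {
  if (!name %in% names(exp$feature_tables))
    stop(sprintf("unknown table '%s'; available: %s", name,
                 paste(names(exp$feature_tables), collapse = ", ")))
  read_feature_table(file.path(exp$root_dir, exp$feature_tables[[name]]),
                     dialect = "generic")
}

#' @rdname experiment_store_table
#' @param empcpds list of `EmpiricalCompound`.
#' @export
experiment_store_empcpds <- function(exp, empcpds, name) {
  if (name %in% names(exp$empcpd_sets))
    stop("empirical compound set name already in use: ", name)
  rel <- file.path("empcpds", paste0(name, ".json"))
  write_empcpd_set(empcpds, file.path(exp$root_dir, rel))
  exp$empcpd_sets[[name]] <- rel
  save_experiment(exp)
}

#' @rdname experiment_store_table
#' @export
experiment_get_empcpds <- function(exp, name) {
  if (!name %in% names(exp$empcpd_sets))
    stop(sprintf("unknown empirical compound set '%s'; available: %s", name,
                 paste(names(exp$empcpd_sets), collapse = ", ")))
  read_empcpd_set(file.path(exp$root_dir, exp$empcpd_sets[[name]]))
}

#' @export
print.Experiment <- function(x, ...) {
  cat(sprintf("Experiment at %s: %d acquisitions, %d tables, %d empcpd sets, %d commands logged\n",
              x$root_dir, length(x$acquisitions), length(x$feature_tables),
              length(x$empcpd_sets), length(x$command_log)))
  invisible(x)
}

#' Generate a plain-text summary report
#'
#' Markdown report covering the acquisition summary, per-stage feature
#' counts, QC metrics of the latest table, annotation counts by level, and
#' the full command timeline.
#'
#' @param exp an `Experiment` with at least one stored table.
#' @param path output path (default `report.md` in the experiment
#'   directory).
#' @return the report path, invisibly.
#' @export
generate_report <- function(exp, path = file.path(exp$root_dir, "report.md")) {
  if (!length(exp$feature_tables)) stop("experiment has no feature tables")
  ln <- c("# Experiment report", "",
          sprintf("Workspace: %s", exp$root_dir), "",
          "## Acquisitions", "")
  types <- table(vapply(exp$acquisitions, `[[`, "", "sample_type"))
  batches <- table(vapply(exp$acquisitions, `[[`, "", "batch"))
  ln <- c(ln, sprintf("- total: %d", length(exp$acquisitions)),
          sprintf("- by type: %s",
                  paste(sprintf("%s=%d", names(types), types), collapse = ", ")),
          sprintf("- by batch: %s",
                  paste(sprintf("%s=%d", names(batches), batches),
                        collapse = ", ")),
          "", "## Feature tables", "")
  for (nm in names(exp$feature_tables)) {
    tb <- experiment_get_table(exp, nm)
    ln <- c(ln, sprintf("- %s: %d features x %d acquisitions", nm,
                        nrow(tb$features), length(tb$acquisitions)))
  }
  last <- names(exp$feature_tables)[length(exp$feature_tables)]
  tb <- experiment_get_table(exp, last)
  if (length(tb$acquisitions) >= 2) {
    m <- acquisition_metrics(tb)
    ln <- c(ln, "", sprintf("## QC metrics (%s)", last), "",
            "| acquisition | features | TIC | median r | z(features) |",
            "|---|---|---|---|---|",
            sprintf("| %s | %d | %.4g | %.4f | %.3f |", m$acquisition,
                    as.integer(m$feature_count), m$tic, m$median_correlation,
                    m$z_feature_count))
  }
  ln <- c(ln, "", "## Annotations by level", "")
  counts <- c("1a" = 0L, "1b" = 0L, "2" = 0L, "4" = 0L)
  for (nm in names(exp$empcpd_sets)) {
    for (ec in experiment_get_empcpds(exp, nm))
      for (a in ec$annotations)
        counts[a$level] <- counts[a$level] + 1L
  }
  ln <- c(ln, sprintf("- level %s: %d", names(counts), counts),
          "", "## Command timeline", "")
  for (rec in exp$command_log) {
    pars <- if (length(rec$parameters))
      paste(sprintf("%s=%s", names(rec$parameters),
                    vapply(rec$parameters, function(p)
                      paste(format(unlist(p)), collapse = "+"), "")),
            collapse = " ")
    else ""
    ln <- c(ln, sprintf("1. [%s] %s %s", rec$timestamp, rec$command, pars))
  }
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}
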