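# Reading and writing the linked tables and pipeline outputs. CSV is the
# reference format (ISO-8601 dates via fwrite); Parquet is available when
# the arrow package is installed.

write_one <- function(dt, path_stem, format) {
  if (format == "csv") {
    path <- paste0(path_stem, ".csv")
    data.table::fwrite(dt, path, dateTimeAs = "ISO")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("format = 'parquet' requires the arrow package", call. = FALSE)
    }
    path <- paste0(path_stem, ".parquet")
    df <- as.data.frame(dt)
    for (col in names(df)) if (inherits(df[[col]], "IDate")) df[[col]] <- as.Date(df[[col]])
    arrow::write_parquet(df, path)
  }
  path
}

read_one <- function(path_stem, format, date_cols = character(0)) {
  if (format == "csv") {
    dt <- data.table::fread(paste0(path_stem, ".csv"), na.strings = c("", "NA"))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("format = 'parquet' requires the arrow package", call. = FALSE)
    }
    dt <- data.table::as.data.table(arrow::read_parquet(paste0(path_stem, ".parquet")))
  }
  for (col in intersect(date_cols, names(dt))) {
    data.table::set(dt, NULL, col, as_nh_date(dt[[col]], col))
  }
  dt
}

#' Write a linked table bundle to a directory
#'
#' Writes `mds`, `enrollment`, `part_a_stays`, `dispensings` and `deaths`
#' as CSV (or Parquet) files with ISO-8601 dates, plus a
#' `study_window.yaml` recording the study window.
#'
#' @param tables an [nh_tables()] bundle.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(tables, "nh_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("mds", "enrollment", "part_a_stays", "dispensings", "deaths")) {
    write_one(tables[[nm]], file.path(dir, nm), format)
  }
  yaml::write_yaml(list(study_start = as.character(tables$study_start),
                        study_end = as.character(tables$study_end)),
                   file.path(dir, "study_window.yaml"))
  invisible(dir)
}

#' Read a linked table bundle from a directory
#'
#' Counterpart of [write_tables()]; the study window comes from
#' `study_window.yaml` unless overridden.
#'
#' @param dir directory holding the table files.
#' @param format `"csv"` (default) or `"parquet"`.
#' @param study_start,study_end optional window override.
#' @return an [nh_tables()] bundle.
#' @export
read_tables <- function(dir, format = c("csv", "parquet"),
                        study_start = NULL, study_end = NULL) {
  format <- match.arg(format)
  if (is.null(study_start) || is.null(study_end)) {
    meta_path <- file.path(dir, "study_window.yaml")
    if (!file.exists(meta_path)) {
      stop(sprintf("no study_window.yaml in %s; pass study_start/study_end", dir),
           call. = FALSE)
    }
    meta <- yaml::read_yaml(meta_path)
    if (is.null(study_start)) study_start <- meta$study_start
    if (is.null(study_end)) study_end <- meta$study_end
  }
  date_cols <- list(mds = "event_date",
                    enrollment = character(0),
                    part_a_stays = c("admit_date", "discharge_date"),
                    dispensings = "fill_date",
                    deaths = "death_date")
  parts <- lapply(names(date_cols), function(nm) {
    read_one(file.path(dir, nm), format, date_cols[[nm]])
  })
  names(parts) <- names(date_cols)
  # fread may narrow types on empty/NA-heavy files; re-assert key classes
  if (!is.character(parts$mds$resident_id)) parts$mds[, resident_id := as.character(resident_id)]
  nh_tables(parts$mds, parts$enrollment, parts$part_a_stays,
            parts$dispensings, parts$deaths, study_start, study_end)
}
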