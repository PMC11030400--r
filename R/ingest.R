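## ingest: reading and validating measurement reports and run logs, and
## writing result tables. No science lives here.

#' Default column mapping for measurement reports
#'
#' Maps the semantic fields of a measurement table to the column names
#' expected in a delimited report. The default is the package's own canonical
#' header; [skyline_column_map()] matches a "Transition Results"-style export
#' from common chromatogram-integration software.
#'
#' @return Named character vector, semantic field -> source column name.
#' @export
default_column_map <- function() {
  c(run_id           = "run_id",
    acquired_at      = "acquired_at",
    peptide          = "peptide",
    precursor_charge = "precursor_charge",
    analyte_class    = "analyte_class",
    precursor_area   = "precursor_area",
    transition_area  = "transition_area",
    rt_min           = "rt_min",
    mass_error_ppm   = "mass_error_ppm",
    iso_m0           = "iso_m0",
    iso_m1           = "iso_m1",
    iso_m2           = "iso_m2")
}

#' @rdname default_column_map
#' @export
skyline_column_map <- function() {
  c(run_id           = "Replicate",
    acquired_at      = "Acquired Time",
    peptide          = "Peptide",
    precursor_charge = "Precursor Charge",
    analyte_class    = "Analyte Class",
    precursor_area   = "Total Area",
    transition_area  = "Total Area Fragment",
    rt_min           = "Retention Time",
    mass_error_ppm   = "Average Mass Error PPM",
    iso_m0           = "Isotope Area M0",
    iso_m1           = "Isotope Area M1",
    iso_m2           = "Isotope Area M2")
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x)))
    qcs_validation_error("unparseable timestamp in 'acquired_at'")
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

read_delimited <- function(path) {
  if (!file.exists(path)) qcs_io_error(paste0("file not found: ", path))
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "#", na.strings = c("NA", ""))
}

#' Parse a per-run, per-analyte measurement report
#'
#' Reads a delimited (tab-separated) post-integration report with one row per
#' (run, precursor) and validates it into a measurement table: the universal
#' exchange unit consumed by the chart, triage and quantification layers.
#' Raw-file parsing and peak integration are out of scope; reports come from
#' external chromatogram-integration software or from
#' [simulate_experiment()].
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param column_map Named character vector mapping the semantic fields named
#'   in [default_column_map()] to the report's column names.
#' @return A tibble of class `measurement_table`, sorted by
#'   (`acquired_at`, `run_id`, `analyte_id`), with an `analyte_id` column of
#'   the form `"PEPTIDE/charge"`. The three isotope-peak areas may be missing
#'   only jointly for a row ("not measured"), never individually.
#' @export
parse_measurement_report <- function(path, column_map = default_column_map()) {
  raw <- read_delimited(path)
  required <- names(default_column_map())
  map <- default_column_map()
  map[names(column_map)] <- column_map
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols) > 0)
    qcs_schema_error(paste0("measurement report is missing required column(s): ",
                            paste(missing_cols, collapse = ", "),
                            " (mapped from: ",
                            paste(map[missing_cols], collapse = ", "), ")"))
  df <- tibble(
    run_id           = as.character(raw[[map["run_id"]]]),
    acquired_at      = parse_timestamp(raw[[map["acquired_at"]]]),
    peptide          = as.character(raw[[map["peptide"]]]),
    precursor_charge = as.integer(raw[[map["precursor_charge"]]]),
    analyte_class    = toupper(as.character(raw[[map["analyte_class"]]])),
    precursor_area   = as.numeric(raw[[map["precursor_area"]]]),
    transition_area  = as.numeric(raw[[map["transition_area"]]]),
    rt_min           = as.numeric(raw[[map["rt_min"]]]),
    mass_error_ppm   = as.numeric(raw[[map["mass_error_ppm"]]]),
    iso_m0           = as.numeric(raw[[map["iso_m0"]]]),
    iso_m1           = as.numeric(raw[[map["iso_m1"]]]),
    iso_m2           = as.numeric(raw[[map["iso_m2"]]])
  )
  df$analyte_id <- paste0(df$peptide, "/", df$precursor_charge)
  validate_measurement_table(df)
}

#' Validate an in-memory measurement table
#'
#' @param df A data frame with the columns of [parse_measurement_report()].
#' @return The validated, sorted `measurement_table` tibble.
#' @export
validate_measurement_table <- function(df) {
  df <- as_tibble(df)
  if (!"analyte_id" %in% names(df))
    df$analyte_id <- paste0(df$peptide, "/", df$precursor_charge)
  bad_class <- !df$analyte_class %in% ANALYTE_CLASSES
  if (any(bad_class))
    qcs_validation_error(paste0("unknown analyte_class: ",
                                paste(unique(df$analyte_class[bad_class]), collapse = ", "),
                                "; allowed: ", paste(ANALYTE_CLASSES, collapse = ", ")))
  for (col in c("precursor_area", "transition_area", "rt_min")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0)
      qcs_validation_error(paste0("negative ", col, " at row(s): ",
                                  paste(head(bad, 5), collapse = ", ")))
  }
  iso <- cbind(df$iso_m0, df$iso_m1, df$iso_m2)
  n_na <- rowSums(is.na(iso))
  partial <- which(n_na > 0 & n_na < 3)
  if (length(partial) > 0)
    qcs_validation_error(paste0("isotope areas must be jointly present or jointly ",
                                "missing; partial rows: ",
                                paste(head(partial, 5), collapse = ", ")))
  bad_iso <- which(!is.na(iso) & iso < 0, arr.ind = TRUE)
  if (nrow(bad_iso) > 0)
    qcs_validation_error(paste0("negative isotope area at row(s): ",
                                paste(head(unique(bad_iso[, 1]), 5), collapse = ", ")))
  key <- paste(df$run_id, df$analyte_id, sep = "\r")
  if (anyDuplicated(key))
    qcs_validation_error(paste0("duplicate (run_id, analyte_id) pair(s): ",
                                paste(head(unique(key[duplicated(key)]), 3),
                                      collapse = "; ")))
  ord <- order(df$acquired_at, df$run_id, df$analyte_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  class(df) <- c("measurement_table", class(df))
  df
}

#' Parse a run-metadata log
#'
#' @param path Path to a tab-delimited run log with columns `run_id`,
#'   `acquired_at`, `run_type`, `batch_id` and optionally `prep_arm`,
#'   `annotation`, `truth_event`. `run_type` is matched case-insensitively
#'   against the four recognised types.
#' @return A tibble of class `run_log` sorted by acquisition time.
#' @export
parse_run_log <- function(path) {
  raw <- read_delimited(path)
  required <- c("run_id", "acquired_at", "run_type", "batch_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    qcs_schema_error(paste0("run log is missing required column(s): ",
                            paste(missing_cols, collapse = ", ")))
  df <- tibble(
    run_id      = as.character(raw$run_id),
    acquired_at = parse_timestamp(raw$acquired_at),
    run_type    = toupper(as.character(raw$run_type)),
    batch_id    = as.character(raw$batch_id),
    prep_arm    = if ("prep_arm" %in% names(raw)) as.character(raw$prep_arm) else NA_character_,
    annotation  = if ("annotation" %in% names(raw)) as.character(raw$annotation) else NA_character_,
    truth_event = if ("truth_event" %in% names(raw)) as.character(raw$truth_event) else NA_character_
  )
  validate_run_log(df)
}

#' Validate an in-memory run log
#'
#' @param df A data frame with at least `run_id`, `acquired_at`, `run_type`,
#'   `batch_id`.
#' @return The validated `run_log` tibble.
#' @export
validate_run_log <- function(df) {
  df <- as_tibble(df)
  for (col in c("prep_arm", "annotation", "truth_event"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$run_type <- toupper(df$run_type)
  bad <- !df$run_type %in% RUN_TYPES
  if (any(bad))
    qcs_validation_error(paste0("unknown run_type: ",
                                paste(unique(df$run_type[bad]), collapse = ", "),
                                "; allowed values: ",
                                paste(RUN_TYPES, collapse = ", ")))
  if (anyDuplicated(df$run_id))
    qcs_validation_error("duplicate run_id in run log")
  ord <- order(df$acquired_at, df$run_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  class(df) <- c("run_log", class(df))
  df
}

## Numeric formatting used by every TSV writer: 15 significant digits so a
## write/parse round trip preserves values well inside 1e-12 relative.
format_number <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.15g", v)
  }, character(1))
  out
}

#' Write a result table to disk
#'
#' Writes any package result table (measurement tables, run logs, chart
#' results, CV tables, triage calls, ...) as tab-separated text or JSON.
#' TSV output uses `.` as the decimal mark, ISO-8601 UTC timestamps, and 15
#' significant digits so that re-parsing reproduces values to at least 12
#' significant digits.
#'
#' @param table A data frame, or a `quant_matrix`.
#' @param path Output file path.
#' @param format `"TSV"` or `"JSON"` (case-insensitive).
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path, format = c("TSV", "JSON")) {
  UseMethod("write_table")
}

#' @export
write_table.data.frame <- function(table, path, format = c("TSV", "JSON")) {
  format <- toupper(match.arg(toupper(format[1]), c("TSV", "JSON")))
  df <- as.data.frame(table)
  ## drop list-columns (e.g. evidence) by serialising them to JSON strings
  for (col in names(df)) {
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], function(x)
        as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)),
        character(1))
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) qcs_io_error(paste0("directory does not exist: ", dir))
  if (format == "JSON") {
    out <- df
    if (inherits(out$acquired_at, "POSIXct"))
      out$acquired_at <- format_timestamp(out$acquired_at)
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", POSIXt = "ISO8601")
    return(invisible(path))
  }
  out <- df
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct")) out[[col]] <- format_timestamp(out[[col]])
    else if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- format_number(out[[col]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    mat <- vapply(out, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }, character(nrow(out)))
    if (nrow(out) == 1) mat <- matrix(mat, nrow = 1)
    writeLines(apply(mat, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
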