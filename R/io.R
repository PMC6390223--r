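# Reading and writing grasp-record tables. One row per trial: design labels
# plus the 3-D thumb and index fingertip contact positions in table
# coordinates (cm).

.record_fields <- c("participant", "material", "orientation_deg", "repetition",
                    "thumb_x", "thumb_y", "thumb_z",
                    "index_x", "index_y", "index_z")

.coord_fields <- c("thumb_x", "thumb_y", "thumb_z",
                   "index_x", "index_y", "index_z")

#' Default column mapping for grasp-record files
#'
#' Maps the canonical field names to the column names found in an input
#' file. The default is the identity mapping; to read a deposition that uses
#' its own dialect, supply e.g.
#' `default_column_mapping(participant = "subj", thumb_x = "tx", ...)`.
#'
#' @param ... canonical field = file column name overrides.
#' @return named character vector, names are the canonical fields.
#' @export
default_column_mapping <- function(...) {
  mapping <- stats::setNames(.record_fields, .record_fields)
  overrides <- c(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), .record_fields)
    if (length(unknown)) {
      stop("unknown record fields in mapping: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    mapping[names(overrides)] <- overrides
  }
  mapping
}

#' Validate a grasp-record tibble
#'
#' Checks the presence of the canonical columns, finite numeric coordinates,
#' and non-degenerate grasps (thumb != index). Offending rows are reported by
#' row number.
#'
#' @param records a tibble of grasp records.
#' @return the validated tibble (invisibly usable in a pipe).
#' @export
validate_records <- function(records) {
  missing <- setdiff(.record_fields, names(records))
  if (length(missing)) {
    stop("missing record columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- character(0)
  for (col in c(.coord_fields, "orientation_deg", "repetition")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
    }
    rows <- which(!is.finite(v))
    if (length(rows)) {
      bad <- c(bad, sprintf("%s non-numeric/non-finite in row(s) %s",
                            col, paste(utils::head(rows, 5), collapse = ", ")))
    }
    records[[col]] <- v
  }
  if (length(bad)) stop("invalid records: ", paste(bad, collapse = "; "), call. = FALSE)
  same <- which(records$thumb_x == records$index_x &
                records$thumb_y == records$index_y &
                records$thumb_z == records$index_z)
  if (length(same)) {
    stop("degenerate grasp (thumb == index) in row(s): ",
         paste(utils::head(same, 5), collapse = ", "), call. = FALSE)
  }
  records$participant <- as.character(records$participant)
  records$material <- as.character(records$material)
  records$repetition <- as.integer(records$repetition)
  tibble::as_tibble(records[, .record_fields])
}

#' Load grasp records from a delimited text file
#'
#' @param path file path; comma-delimited with a header row by default.
#' @param column_mapping see [default_column_mapping()]. Rows that fail
#'   validation are reported with their data row numbers (header excluded).
#' @param delim field delimiter.
#' @param verbose print a per-stage count of rows read.
#' @return a validated grasp-record tibble.
#' @export
load_records <- function(path, column_mapping = default_column_mapping(),
                         delim = ",", verbose = FALSE) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(unname(column_mapping), names(raw))
  if (length(missing)) {
    stop("input file ", path, " lacks mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- raw[, unname(column_mapping)]
  names(out) <- names(column_mapping)
  out <- validate_records(out)
  if (verbose) message(nrow(out), " grasp records read from ", path)
  out
}

#' Write grasp records to a delimited text file
#'
#' @param records grasp-record tibble.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  records <- validate_records(records)
  readr::write_delim(records, path, delim = delim)
  invisible(path)
}
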