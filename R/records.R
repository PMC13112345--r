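RECORD_COLUMNS <- c(time = "numeric", replica_id = "character",
                    replicate_index = "integer", pH = "numeric",
                    window_id = "character", z_nm = "numeric",
                    state = "character", bias_kJmol = "numeric",
                    equilibration_flag = "logical")

#' Write / read record tables
#'
#' Record tables are tab-separated text with a header line and optional
#' `#`-prefixed provenance lines before it; all schema columns (see
#' [frame()]) plus any extra columns (e.g. `insertion_A`) round-trip
#' losslessly.
#'
#' @param records Record table.
#' @param path File path.
#' @param provenance Character vector of provenance lines to place at the
#'   top of the file (written with a `#` prefix).
#' @return `write_records` returns `path` invisibly; `read_records` the
#'   record table (with any provenance lines in attribute `provenance`).
#' @export
write_records <- function(records, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (!length(body)) stop("no table found in ", path)
  first_body <- body[1]
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(names(RECORD_COLUMNS), names(df))
  if (length(missing_cols))
    stop("record file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  convert <- function(x, type, col) {
    val <- switch(type,
                  numeric = suppressWarnings(as.numeric(x)),
                  integer = suppressWarnings(as.integer(x)),
                  logical = as.logical(x),
                  character = x)
    bad <- which(!is.na(x) & x != "NA" & is.na(val))
    if (length(bad))
      stop(sprintf("type mismatch in column '%s' at line %d of %s",
                   col, first_body + bad[1], path))
    val
  }
  for (col in names(df)) {
    type <- if (col %in% names(RECORD_COLUMNS)) RECORD_COLUMNS[[col]]
            else "numeric"
    if (col %in% names(RECORD_COLUMNS) || !anyNA(suppressWarnings(
          as.numeric(df[[col]][df[[col]] != "NA"]))))
      df[[col]] <- convert(df[[col]], type, col)
  }
  if (length(prov)) attr(df, "provenance") <- sub("^# ?", "", prov)
  df
}

#' Write an exchange log or profile table
#'
#' Plain TSV writer used by the command-line layer for exchange logs,
#' PMFs, and profile tables; `#` metadata lines go first.
#'
#' @param x Data.frame.
#' @param path File path.
#' @param meta Character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
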