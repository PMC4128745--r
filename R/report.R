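#' Write an analysis report
#'
#' Serializes a (possibly nested) list of results to JSON, or a flat
#' data frame to CSV. JSON keys keep their insertion order; rate constants
#' and frequencies should be pre-formatted with \code{\link{format_sci}}
#' where the conventional 2-significant-digit scientific notation is
#' wanted.
#'
#' @param results Named list (JSON) or data frame (CSV).
#' @param path Output file path.
#' @param format \code{"json"} (default) or \code{"csv"}.
#' @param overwrite Allow overwriting an existing file (default FALSE).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         overwrite = FALSE) {
  format <- match.arg(format)
  if (file.exists(path) && !overwrite) {
    pc_stop(sprintf("output file exists (use overwrite = TRUE): %s", path),
            class = "phagechar_io_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    pc_stop(sprintf("output directory does not exist: %s", dir),
            class = "phagechar_io_error")
  }
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    if (!is.data.frame(results)) {
      pc_stop("CSV output requires a data frame")
    }
    utils::write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON report back
#'
#' @param path Path written by \code{\link{write_report}}.
#' @return The deserialized list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
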