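#' Construct a titer series
#'
#' A titer series is the raw result of a timed plating assay: phage titers
#' (pfu/ml) sampled at increasing times, optionally across several
#' replicates. It is the common input to the adsorption and one-step growth
#' estimators.
#'
#' @param time_min Numeric vector of sampling times in minutes,
#'   non-negative and strictly increasing within each replicate.
#' @param titer_pfu_ml Numeric vector of phage titers (pfu/ml), >= 0.
#' @param replicate Integer replicate labels (recycled if length 1).
#' @param dilution_plated Optional dimensionless dilution factor per row.
#' @param volume_plated Optional plated volume (ml) per row.
#' @return A data frame of class \code{"titer_series"} with columns
#'   \code{time_min}, \code{titer_pfu_ml}, \code{replicate} (plus the
#'   optional plating columns), sorted by replicate then time.
#' @examples
#' titer_series(c(3, 5, 8, 10, 15, 20), c(7e5, 5.5e5, 3.8e5, 3e5, 1.5e5, 1.2e5))
#' @export
titer_series <- function(time_min, titer_pfu_ml, replicate = 1L,
                         dilution_plated = NULL, volume_plated = NULL) {
  if (length(time_min) == 0L) pc_stop("titer series must contain at least one sample")
  if (length(time_min) != length(titer_pfu_ml)) {
    pc_stop("`time_min` and `titer_pfu_ml` must have the same length")
  }
  time_min <- as.numeric(time_min)
  titer_pfu_ml <- as.numeric(titer_pfu_ml)
  if (anyNA(time_min) || anyNA(titer_pfu_ml)) pc_stop("times and titers must be non-missing")
  if (any(time_min < 0)) pc_stop("times must be non-negative")
  if (any(titer_pfu_ml < 0)) pc_stop("titers must be non-negative")
  replicate <- rep_len(as.integer(replicate), length(time_min))

  df <- data.frame(
    time_min = time_min,
    titer_pfu_ml = titer_pfu_ml,
    replicate = replicate
  )
  if (!is.null(dilution_plated)) df$dilution_plated <- rep_len(as.numeric(dilution_plated), nrow(df))
  if (!is.null(volume_plated)) df$volume_plated <- rep_len(as.numeric(volume_plated), nrow(df))

  df <- df[order(df$replicate, df$time_min), , drop = FALSE]
  rownames(df) <- NULL
  for (r in unique(df$replicate)) {
    tt <- df$time_min[df$replicate == r]
    if (anyDuplicated(tt)) {
      pc_stop(sprintf("duplicated sampling time within replicate %d", r))
    }
  }
  class(df) <- c("titer_series", "data.frame")
  df
}

#' @export
print.titer_series <- function(x, ...) {
  cat(sprintf("<titer_series> %d samples, %d replicate(s), t = %g..%g min\n",
              nrow(x), length(unique(x$replicate)),
              min(x$time_min), max(x$time_min)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a titer-series CSV
#'
#' Expects the assay CSV schema used throughout the package: columns
#' \code{assay,phage_id,replicate,time_min,titer_pfu_ml} with a mandatory
#' header, comma separation, UTF-8, \code{'.'} decimal. Rows are sorted by
#' time on load; each (assay, phage) combination becomes one
#' \code{\link{titer_series}}.
#'
#' @param path Path to the CSV file.
#' @return Named list of \code{titer_series}, one per
#'   \code{assay:phage_id} combination.
#' @export
read_titer_csv <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("assay", "phage_id", "replicate", "time_min", "titer_pfu_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    pc_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
            class = "phagechar_schema_error")
  }
  if (nrow(df) == 0L) pc_stop("file contains no data rows", class = "phagechar_schema_error")
  for (col in c("time_min", "titer_pfu_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      pc_stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                      col, bad[1], df[[col]][bad[1]]),
              class = "phagechar_schema_error")
    }
    df[[col]] <- v
  }
  key <- paste(df$assay, df$phage_id, sep = ":")
  lapply(split(df, key), function(d) {
    titer_series(d$time_min, d$titer_pfu_ml, replicate = d$replicate)
  })
}
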