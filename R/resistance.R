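#' Frequency of phage-resistant mutant cells
#'
#' In the resistant-mutant assay a culture is challenged with phage at high
#' MOI and plated; surviving colonies are (putative) resistant mutants. The
#' per-replicate frequency is colonies / cells plated; the assay-level
#' estimate is the mean across replicates with its sample standard
#' deviation.
#'
#' @name resistance_assay
NULL

#' Construct resistance-plating records
#'
#' @param colonies Integer colony counts per replicate, >= 0.
#' @param cells_plated Cells plated per replicate (culture cfu/ml x plated
#'   volume in ml), > 0.
#' @param replicate Optional replicate labels.
#' @param moi_challenge Optional challenge MOI (recorded, not used in the
#'   estimate).
#' @return Data frame of class \code{"resistance_plating"}.
#' @export
resistance_plating <- function(colonies, cells_plated, replicate = NULL,
                               moi_challenge = NA_real_) {
  if (length(colonies) == 0L) pc_stop("at least one plating is required")
  if (any(is.na(colonies)) || any(colonies < 0)) pc_stop("`colonies` must be >= 0")
  cells_plated <- rep_len(as.numeric(cells_plated), length(colonies))
  if (any(is.na(cells_plated)) || any(cells_plated <= 0)) {
    pc_stop("`cells_plated` must be > 0")
  }
  if (any(colonies > cells_plated)) {
    pc_stop("`colonies` cannot exceed `cells_plated`")
  }
  if (is.null(replicate)) replicate <- seq_along(colonies)
  df <- data.frame(
    replicate = as.integer(replicate),
    colonies = as.numeric(colonies),
    cells_plated = cells_plated,
    moi_challenge = rep_len(as.numeric(moi_challenge), length(colonies))
  )
  class(df) <- c("resistance_plating", "data.frame")
  df
}

#' Mutant frequency from colony counts
#'
#' @param platings A \code{\link{resistance_plating}} data frame (or any
#'   data frame with \code{colonies} and \code{cells_plated} columns).
#' @return List with \code{mean}, \code{sd} (sample SD, n - 1 denominator;
#'   \code{NA} for a single replicate) and \code{per_replicate}
#'   frequencies.
#' @examples
#' p <- resistance_plating(c(12, 10, 14), 1e8)
#' mutant_frequency(p)$mean  # 1.2e-7
#' @export
mutant_frequency <- function(platings) {
  if (!is.data.frame(platings) ||
      !all(c("colonies", "cells_plated") %in% names(platings))) {
    pc_stop("`platings` must have `colonies` and `cells_plated` columns")
  }
  if (nrow(platings) == 0L) pc_stop("at least one plating is required")
  if (any(platings$cells_plated <= 0)) pc_stop("`cells_plated` must be > 0")
  freq <- platings$colonies / platings$cells_plated
  list(
    mean = mean(freq),
    sd = if (length(freq) > 1L) stats::sd(freq) else NA_real_,
    per_replicate = freq
  )
}

#' Read a resistance-assay CSV
#'
#' Expected columns: \code{phage_id,replicate,colonies,cells_plated}.
#'
#' @param path Path to the CSV.
#' @return Named list of \code{\link{resistance_plating}} objects, one per
#'   phage.
#' @export
read_resistance_csv <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("phage_id", "replicate", "colonies", "cells_plated")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    pc_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
            class = "phagechar_schema_error")
  }
  lapply(split(df, df$phage_id), function(d) {
    resistance_plating(d$colonies, d$cells_plated, replicate = d$replicate)
  })
}
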