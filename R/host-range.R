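#' Host-range matrices and efficiency of plating
#'
#' A host-range study scores every (strain, phage) pair with one of three
#' activity calls: \code{propagates} (productive plaque formation),
#' \code{adsorbs_only} (adsorption detected, e.g. by parallel streaks, but
#' no propagation) or \code{resistant}. Strains that a phage "adsorbs on"
#' are those with call \code{propagates} or \code{adsorbs_only}. For
#' propagating pairs the efficiency of plating (EOP) quantifies relative
#' productivity.
#'
#' @name host_range
NULL

ACTIVITY_CALLS <- c("propagates", "adsorbs_only", "resistant")

#' Efficiency of plating
#'
#' EOP is the phage titer obtained on a test strain divided by the titer on
#' the propagation host.
#'
#' @param test_titer Titer on the test strain (pfu/ml), >= 0.
#' @param host_titer Titer on the propagation host (pfu/ml), > 0.
#' @return Dimensionless EOP (vectorized).
#' @examples
#' eop(1e4, 1e9)  # 1e-5
#' @export
eop <- function(test_titer, host_titer) {
  if (any(is.na(host_titer)) || any(host_titer <= 0)) {
    pc_stop("`host_titer` must be positive")
  }
  if (any(is.na(test_titer)) || any(test_titer < 0)) {
    pc_stop("`test_titer` must be non-negative")
  }
  test_titer / host_titer
}

#' Construct a host-range matrix
#'
#' @param calls Data frame with columns \code{strain_id}, \code{phage_id},
#'   \code{call} (one of \code{propagates}, \code{adsorbs_only},
#'   \code{resistant}) and optionally \code{eop}. Every
#'   (strain, phage) pair must appear exactly once.
#' @param strains Optional data frame of strain metadata with at least
#'   \code{strain_id} and \code{species}; defaults to the strains present
#'   in \code{calls} (using a \code{species} column there if present).
#' @return An object of class \code{"host_range_matrix"}.
#' @export
host_range_matrix <- function(calls, strains = NULL) {
  req <- c("strain_id", "phage_id", "call")
  missing <- setdiff(req, names(calls))
  if (length(missing)) {
    pc_stop(sprintf("`calls` missing column(s): %s", paste(missing, collapse = ", ")))
  }
  calls$call <- as.character(calls$call)
  bad <- setdiff(unique(calls$call), ACTIVITY_CALLS)
  if (length(bad)) {
    pc_stop(sprintf("unknown activity call(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"eop" %in% names(calls)) calls$eop <- NA_real_
  # EOP values are often recorded as scientific-notation strings ("1.0E-5")
  calls$eop <- suppressWarnings(as.numeric(calls$eop))
  if (any(!is.na(calls$eop) & calls$eop < 0)) pc_stop("EOP values must be >= 0")
  if (any(!is.na(calls$eop) & calls$call != "propagates")) {
    pc_stop("EOP may only be recorded for pairs with call 'propagates'")
  }

  if (is.null(strains)) {
    if ("species" %in% names(calls)) {
      strains <- unique(calls[, c("strain_id", "species")])
    } else {
      strains <- data.frame(strain_id = unique(calls$strain_id), species = NA_character_)
    }
  }
  if (anyDuplicated(strains$strain_id)) pc_stop("duplicated strain_id in `strains`")

  phages <- sort(unique(calls$phage_id))
  key <- paste(calls$strain_id, calls$phage_id)
  expected <- paste(rep(strains$strain_id, each = length(phages)),
                    rep(phages, times = nrow(strains)))
  if (anyDuplicated(key)) pc_stop("duplicate (strain, phage) call")
  if (!setequal(key, expected)) {
    pc_stop("call grid incomplete: every (strain, phage) pair must appear exactly once")
  }
  structure(list(strains = strains, calls = calls, phages = phages),
            class = "host_range_matrix")
}

#' @export
print.host_range_matrix <- function(x, ...) {
  cat(sprintf("<host_range_matrix> %d strains x %d phages\n",
              nrow(x$strains), length(x$phages)))
  print(table(x$calls$phage_id, x$calls$call))
  invisible(x)
}

filter_strains <- function(matrix, species_filter = NULL) {
  strains <- matrix$strains
  if (!is.null(species_filter)) {
    strains <- strains[strains$species %in% species_filter, , drop = FALSE]
  }
  if (nrow(strains) == 0L) pc_stop("species filter matches no strains")
  strains
}

#' Summarize a phage's host range
#'
#' Counts and percentages of strains the phage propagates on and adsorbs on
#' (adsorbs = \code{propagates} or \code{adsorbs_only}). Percentages are
#' reported to one decimal, rounding halves up.
#'
#' @param matrix A \code{\link{host_range_matrix}}.
#' @param phage_id Phage to summarize.
#' @param species_filter Optional character vector of species to keep.
#' @return List with \code{n}, \code{n_propagates}, \code{n_adsorbs},
#'   \code{pct_propagates}, \code{pct_adsorbs}.
#' @export
summarize_host_range <- function(matrix, phage_id, species_filter = NULL) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  if (!phage_id %in% matrix$phages) pc_stop(sprintf("unknown phage_id '%s'", phage_id))
  strains <- filter_strains(matrix, species_filter)
  calls <- matrix$calls
  calls <- calls[calls$phage_id == phage_id & calls$strain_id %in% strains$strain_id, ]
  n <- nrow(calls)
  n_prop <- sum(calls$call == "propagates")
  n_ads <- sum(calls$call %in% c("propagates", "adsorbs_only"))
  list(
    n = n,
    n_propagates = n_prop,
    n_adsorbs = n_ads,
    pct_propagates = round_half_up(100 * n_prop / n, 1),
    pct_adsorbs = round_half_up(100 * n_ads / n, 1)
  )
}

#' Joint activity of two phages across strains
#'
#' Partitions the strains into those on which both phages propagate, those
#' fully resistant to both, and the remainder on which exactly one phage
#' shows activity (or neither propagates but some adsorption occurs).
#'
#' @param matrix A \code{\link{host_range_matrix}}.
#' @param phage_a,phage_b The two phage ids.
#' @param species_filter Optional character vector of species to keep.
#' @return List of counts \code{both_propagate},
#'   \code{exactly_one_active}, \code{both_resistant}, and \code{n}; the
#'   three categories partition the n strains.
#' @export
joint_activity <- function(matrix, phage_a, phage_b, species_filter = NULL) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  for (p in c(phage_a, phage_b)) {
    if (!p %in% matrix$phages) pc_stop(sprintf("unknown phage_id '%s'", p))
  }
  strains <- filter_strains(matrix, species_filter)
  calls <- matrix$calls[matrix$calls$strain_id %in% strains$strain_id, ]
  ca <- calls[calls$phage_id == phage_a, ]
  cb <- calls[calls$phage_id == phage_b, ]
  ca <- ca[match(strains$strain_id, ca$strain_id), ]
  cb <- cb[match(strains$strain_id, cb$strain_id), ]
  if (anyNA(ca$call) || anyNA(cb$call)) pc_stop("missing calls for some strains")
  both_prop <- sum(ca$call == "propagates" & cb$call == "propagates")
  both_res <- sum(ca$call == "resistant" & cb$call == "resistant")
  n <- nrow(strains)
  list(
    both_propagate = both_prop,
    exactly_one_active = n - both_prop - both_res,
    both_resistant = both_res,
    n = n
  )
}

#' Read a host-range CSV
#'
#' Expected columns: \code{strain_id,species,rep_profile,oxa51,oxa23,}
#' \code{carbapenem,phage_id,call,eop} (metadata columns may be empty).
#' EOP may be written in scientific notation.
#'
#' @param path Path to the CSV.
#' @return A \code{\link{host_range_matrix}}.
#' @export
read_host_range_csv <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("strain_id", "phage_id", "call")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    pc_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
            class = "phagechar_schema_error")
  }
  meta_cols <- intersect(
    c("strain_id", "species", "rep_profile", "oxa51", "oxa23", "carbapenem"),
    names(df)
  )
  strains <- unique(df[, meta_cols, drop = FALSE])
  host_range_matrix(df[, intersect(c("strain_id", "phage_id", "call", "eop"), names(df))],
                    strains = strains)
}
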