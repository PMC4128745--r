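#' Appelmans broth assays: dilution design, endpoints, cocktail comparison
#'
#' The Appelmans method titrates phage lytic activity in broth: serial
#' tenfold dilutions of a phage stock (and, for cocktail studies, of a
#' phage mixture) are inoculated with a fixed bacterial concentration and
#' scored by culture turbidity (OD600) after 24 and 48 h. A tube is called
#' lysed when its mean OD600 falls below a threshold (default 0.1).
#'
#' @name appelmans
NULL

#' Define a serial-dilution plan
#'
#' @param stock_titer Phage stock titer (pfu/ml), > 0.
#' @param dilution_exponents Integer exponents of the tenfold dilutions
#'   (negative, strictly decreasing), e.g. \code{-2:-9} for dilutions
#'   1e-2 .. 1e-9.
#' @param bacteria Bacterial concentration added to every tube (cfu/ml),
#'   > 0.
#' @param tube_volume Tube volume in ml (recorded; default 5).
#' @return List of class \code{"dilution_plan"}.
#' @examples
#' plan <- dilution_plan(1e9, -2:-9, bacteria = 1e5)
#' sapply(plan$dilution_exponents, function(e) moi_for_dilution(plan, e))
#' @export
dilution_plan <- function(stock_titer, dilution_exponents = -2:-9,
                          bacteria = 1e5, tube_volume = 5) {
  if (stock_titer <= 0) pc_stop("`stock_titer` must be > 0")
  if (bacteria <= 0) pc_stop("`bacteria` must be > 0")
  dilution_exponents <- as.integer(dilution_exponents)
  if (any(diff(dilution_exponents) >= 0)) {
    pc_stop("`dilution_exponents` must be strictly decreasing")
  }
  structure(list(
    stock_titer = stock_titer,
    dilution_exponents = dilution_exponents,
    bacteria = bacteria,
    tube_volume = tube_volume
  ), class = "dilution_plan")
}

#' MOI of one tube in a dilution plan
#'
#' MOI = stock_titer x 10^exponent / bacteria.
#'
#' @param plan A \code{\link{dilution_plan}}.
#' @param exponent One of the plan's dilution exponents.
#' @return Dimensionless MOI.
#' @export
moi_for_dilution <- function(plan, exponent) {
  stopifnot(inherits(plan, "dilution_plan"))
  if (!exponent %in% plan$dilution_exponents) {
    pc_stop(sprintf("exponent %d is not part of the dilution plan", exponent))
  }
  plan$stock_titer * 10^exponent / plan$bacteria
}

#' Construct an OD600 table
#'
#' Long-format container for Appelmans OD600 readings. \code{condition} is
#' one of \code{phage_a}, \code{phage_b}, \code{mixture}, \code{control};
#' the control has no dilution dimension (\code{dilution_exponent = NA}).
#'
#' @param df Data frame with columns \code{condition},
#'   \code{dilution_exponent}, \code{time_h}, \code{replicate},
#'   \code{od600}.
#' @return The validated data frame with class \code{"od_table"}.
#' @export
od_table <- function(df) {
  req <- c("condition", "dilution_exponent", "time_h", "replicate", "od600")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    pc_stop(sprintf("`df` missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(is.na(df$od600)) || any(df$od600 < 0)) pc_stop("OD600 must be >= 0")
  ctrl <- df$condition == "control"
  if (any(!is.na(df$dilution_exponent[ctrl]))) {
    pc_stop("control rows must have dilution_exponent = NA")
  }
  if (any(is.na(df$dilution_exponent[!ctrl]))) {
    pc_stop("phage rows must have a dilution_exponent")
  }
  class(df) <- c("od_table", "data.frame")
  df
}

# Mean OD per (condition, exponent) at a given time.
od_means <- function(od, condition, time_h) {
  d <- od[od$condition == condition & od$time_h == time_h, , drop = FALSE]
  if (nrow(d) == 0L) {
    pc_stop(sprintf("no rows for condition '%s' at %g h", condition, time_h))
  }
  agg <- stats::aggregate(od600 ~ dilution_exponent, data = d, FUN = mean)
  agg[order(agg$dilution_exponent), ]
}

#' Lysis endpoint of a condition
#'
#' The endpoint is the most dilute tube (smallest, i.e. most negative,
#' exponent) whose replicate-mean OD600 is below the lysis threshold.
#'
#' @param od An \code{\link{od_table}}.
#' @param condition Condition name.
#' @param time_h Readout time (hours).
#' @param threshold Lysis threshold on OD600 (default 0.1).
#' @return The endpoint exponent, or \code{NA} if no tube is below
#'   threshold.
#' @export
lysis_endpoint <- function(od, condition, time_h, threshold = 0.1) {
  stopifnot(inherits(od, "od_table"))
  m <- od_means(od, condition, time_h)
  below <- m$dilution_exponent[m$od600 < threshold]
  if (!length(below)) return(NA_integer_)
  as.integer(min(below))
}

#' Stability of lytic activity in broth
#'
#' A phage (or mixture) is called stable when every tube at or above a
#' minimum MOI keeps its replicate-mean OD600 below the lysis threshold at
#' the stated readout time (default: below 0.1 after 48 h down to MOI
#' 0.01).
#'
#' @param od An \code{\link{od_table}}.
#' @param condition Condition name.
#' @param plan The \code{\link{dilution_plan}} used, to map exponents to
#'   MOI.
#' @param min_moi Minimum MOI the criterion must hold down to (default
#'   0.01).
#' @param time_h Readout time (default 48).
#' @param threshold Lysis threshold (default 0.1).
#' @return Logical stability call.
#' @export
stability_call <- function(od, condition, plan, min_moi = 0.01,
                           time_h = 48, threshold = 0.1) {
  stopifnot(inherits(od, "od_table"), inherits(plan, "dilution_plan"))
  m <- od_means(od, condition, time_h)
  moi <- vapply(m$dilution_exponent, function(e) moi_for_dilution(plan, e), numeric(1))
  keep <- moi >= min_moi
  if (!any(keep)) pc_stop("no tubes at or above `min_moi` in the table")
  all(m$od600[keep] < threshold)
}

#' Compare a phage mixture with its single-phage components
#'
#' For each dilution, the signed OD600 difference between the mixture and
#' the better (lower-OD) single phage is computed, together with the
#' fraction of dilutions at which the mixture is at least as lytic as both
#' singles.
#'
#' @param od An \code{\link{od_table}} containing conditions
#'   \code{phage_a}, \code{phage_b} and \code{mixture}.
#' @param time_h Readout time.
#' @return List with \code{per_dilution} (data frame: exponent, mean OD of
#'   each condition, \code{diff_vs_best} = mixture - min(singles)) and
#'   \code{fraction_mixture_best} in [0, 1].
#' @export
compare_conditions <- function(od, time_h) {
  stopifnot(inherits(od, "od_table"))
  for (cond in c("phage_a", "phage_b", "mixture")) {
    if (!any(od$condition == cond & od$time_h == time_h)) {
      pc_stop(sprintf("condition '%s' missing at %g h", cond, time_h))
    }
  }
  a <- od_means(od, "phage_a", time_h)
  b <- od_means(od, "phage_b", time_h)
  m <- od_means(od, "mixture", time_h)
  exps <- sort(unique(c(a$dilution_exponent, b$dilution_exponent, m$dilution_exponent)),
               decreasing = TRUE)
  if (!all(exps %in% a$dilution_exponent) || !all(exps %in% b$dilution_exponent) ||
      !all(exps %in% m$dilution_exponent)) {
    pc_stop("conditions cover different dilution sets")
  }
  oda <- a$od600[match(exps, a$dilution_exponent)]
  odb <- b$od600[match(exps, b$dilution_exponent)]
  odm <- m$od600[match(exps, m$dilution_exponent)]
  per <- data.frame(
    dilution_exponent = exps,
    od_phage_a = oda,
    od_phage_b = odb,
    od_mixture = odm,
    diff_vs_best = odm - pmin(oda, odb)
  )
  list(
    per_dilution = per,
    fraction_mixture_best = mean(odm <= oda & odm <= odb)
  )
}

#' Read an Appelmans OD600 CSV
#'
#' Expected columns:
#' \code{condition,dilution_exponent,time_h,replicate,od600}.
#'
#' @param path Path to the CSV.
#' @return An \code{\link{od_table}}.
#' @export
read_od_csv <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("condition", "dilution_exponent", "time_h", "replicate", "od600")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    pc_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
            class = "phagechar_schema_error")
  }
  od_table(df)
}
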