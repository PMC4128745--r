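#' Adsorption and one-step growth analysis
#'
#' Tools to turn raw adsorption and one-step growth titer series into the
#' classical infection parameters: the adsorption rate constant k (Adams),
#' the latent period and the burst size.
#'
#' @name kinetics
NULL

# Collapse a multi-replicate series to per-time mean titers.
replicate_mean <- function(series) {
  stopifnot(inherits(series, "titer_series"))
  if (length(unique(series$replicate)) == 1L) return(series)
  agg <- stats::aggregate(titer_pfu_ml ~ time_min, data = series, FUN = mean)
  agg <- agg[order(agg$time_min), ]
  titer_series(agg$time_min, agg$titer_pfu_ml, replicate = 1L)
}

new_adsorption_result <- function(fractions, p0, B = NA_real_, k = NA_real_,
                                  residual_fraction = NA_real_, fit_window = NULL,
                                  mode = NA_character_, warnings = character()) {
  structure(
    list(
      fractions = fractions, p0 = p0, B = B, k = k,
      residual_fraction = residual_fraction,
      fit_window = fit_window, mode = mode, warnings = warnings
    ),
    class = "adsorption_result"
  )
}

#' @export
print.adsorption_result <- function(x, ...) {
  cat("<adsorption_result>\n")
  if (!is.na(x$k)) {
    cat(sprintf("  k = %s ml/min (mode: %s)\n", format_sci(x$k), x$mode))
  }
  if (!is.na(x$residual_fraction)) {
    cat(sprintf("  residual unadsorbable fraction r = %.3f\n", x$residual_fraction))
  }
  cat(sprintf("  %d time points, P0 = %s pfu/ml\n", nrow(x$fractions), format_sci(x$p0)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Fraction of non-adsorbed phage over time
#'
#' Converts a free-phage titer series from an adsorption assay into the
#' fraction of non-adsorbed phage P(t)/P0. The reported fraction is clamped
#' to [0, 1] (counting noise can push the ratio slightly above 1); the raw
#' ratio is preserved in the \code{raw_ratio} column.
#'
#' @param series A \code{\link{titer_series}} of free-phage titers.
#' @param p0 Initial phage titer P0 (pfu/ml), > 0.
#' @return An \code{adsorption_result} whose \code{fractions} element is a
#'   data frame with \code{time_min}, \code{fraction} (clamped) and
#'   \code{raw_ratio}.
#' @examples
#' s <- titer_series(c(3, 5, 8, 10, 15, 20), 1e6 * exp(-0.12 * c(3, 5, 8, 10, 15, 20)))
#' adsorption_fractions(s, p0 = 1e6)
#' @export
adsorption_fractions <- function(series, p0) {
  if (!inherits(series, "titer_series")) pc_stop("`series` must be a titer_series")
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0) {
    pc_stop("`p0` must be a single positive number")
  }
  series <- replicate_mean(series)
  raw <- series$titer_pfu_ml / p0
  fractions <- data.frame(
    time_min = series$time_min,
    fraction = pmin(pmax(raw, 0), 1),
    raw_ratio = raw
  )
  new_adsorption_result(fractions, p0 = p0)
}

# Pre-plateau fitting window: keep points up to and including the first
# sample whose fraction drops by < `flat_tol` relative to the previous
# one. Once the curve flattens (residual unadsorbable phage) the log-linear
# model no longer applies.
pre_plateau_window <- function(fraction, flat_tol = 0.05) {
  n <- length(fraction)
  if (n <= 1L) return(seq_len(n))
  for (i in 2:n) {
    prev <- fraction[i - 1]
    drop <- if (prev > 0) (prev - fraction[i]) / prev else 0
    if (drop < flat_tol) return(seq_len(i))
  }
  seq_len(n)
}

#' Fit the adsorption rate constant (Adams)
#'
#' Under first-order adsorption to a fixed host concentration B (cfu/ml),
#' free phage decay as P(t) = P0 exp(-k B t). The rate constant k (ml/min)
#' is estimated either from a single time point,
#' k = ln(P0 / P(t*)) / (B t*), or by through-origin least squares of
#' ln(P/P0) against t over the pre-plateau window. With
#' \code{allow_residual = TRUE} the model
#' P/P0 = r + (1 - r) exp(-k B t) is fitted instead, where r is a residual
#' non-adsorbable fraction.
#'
#' @param series A \code{\link{titer_series}} of free-phage titers.
#' @param B Host concentration (cfu/ml), > 0.
#' @param p0 Initial phage titer (pfu/ml), > 0.
#' @param mode \code{"regression"} (default) or \code{"single_point"}.
#' @param allow_residual Fit the residual-fraction model (regression mode).
#' @param t_star Time point for single-point mode; defaults to the time of
#'   maximal adsorption (minimum fraction).
#' @param flat_tol Relative per-step drop below which the curve is deemed
#'   flat when choosing the regression window (default 0.05).
#' @return An \code{adsorption_result} with \code{k} (ml/min),
#'   \code{residual_fraction} (NA unless fitted), and the fit window used.
#' @examples
#' # the classical single-point calculation: 85% adsorbed at 15 min on 1e8 cfu/ml
#' s <- titer_series(15, 1.5e5)
#' fit_adsorption_constant(s, B = 1e8, p0 = 1e6, mode = "single_point")$k
#' @export
fit_adsorption_constant <- function(series, B, p0,
                                    mode = c("regression", "single_point"),
                                    allow_residual = FALSE, t_star = NULL,
                                    flat_tol = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B <= 0) {
    pc_stop("`B` must be a single positive host concentration (cfu/ml)")
  }
  res <- adsorption_fractions(series, p0)
  frac <- res$fractions
  warnings <- character()

  if (all(frac$raw_ratio >= 1)) {
    warnings <- "all fractions >= 1: no detectable adsorption, k set to 0"
    out <- new_adsorption_result(frac, p0, B, k = 0, mode = mode, warnings = warnings)
    return(out)
  }

  if (mode == "single_point") {
    usable <- which(frac$raw_ratio > 0 & frac$time_min > 0)
    if (!length(usable)) pc_stop("no usable (positive-fraction, t > 0) point for single-point mode")
    if (is.null(t_star)) {
      i <- usable[which.min(frac$raw_ratio[usable])]
    } else {
      i <- which(frac$time_min == t_star)
      if (!length(i)) pc_stop(sprintf("t_star = %g is not a sampled time", t_star))
      if (frac$raw_ratio[i] <= 0) pc_stop("fraction at t_star is zero; cannot take log")
    }
    k <- log(1 / frac$raw_ratio[i]) / (B * frac$time_min[i])
    return(new_adsorption_result(frac, p0, B, k = max(k, 0), fit_window = i,
                                 mode = mode, warnings = warnings))
  }

  # regression mode
  if (allow_residual) {
    ok <- frac$raw_ratio >= 0
    d <- data.frame(t = frac$time_min[ok], f = frac$raw_ratio[ok])
    if (nrow(d) < 3L) pc_stop("residual-fraction fit needs at least 3 points")
    k0 <- log(1 / max(min(d$f), 1e-6)) / (B * max(d$t))
    fit <- minpack.lm::nlsLM(
      f ~ r + (1 - r) * exp(-k * B * t),
      data = d,
      start = list(r = max(min(d$f) * 0.9, 1e-4), k = max(k0, 1e-12)),
      lower = c(r = 0, k = 0), upper = c(r = 1, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    est <- stats::coef(fit)
    return(new_adsorption_result(frac, p0, B, k = unname(est["k"]),
                                 residual_fraction = unname(est["r"]),
                                 fit_window = which(ok), mode = "regression_residual",
                                 warnings = warnings))
  }

  win <- pre_plateau_window(frac$raw_ratio, flat_tol = flat_tol)
  keep <- win[frac$raw_ratio[win] > 0 & frac$time_min[win] > 0]
  if (length(keep) < length(win[frac$time_min[win] > 0])) {
    warnings <- c(warnings, "non-positive fractions excluded from log fit")
  }
  if (length(keep) < 2L) pc_stop("need at least 2 usable pre-plateau points for regression")
  t <- frac$time_min[keep]
  y <- log(frac$raw_ratio[keep])
  slope <- sum(t * y) / sum(t^2)      # least squares through the origin
  k <- max(-slope / B, 0)
  new_adsorption_result(frac, p0, B, k = k, fit_window = keep,
                        mode = mode, warnings = warnings)
}

#' Estimate the latent period from a one-step growth curve
#'
#' The latent period is the interval between adsorption and the first
#' release of progeny. Operationally: the baseline titer is the mean of the
#' two earliest samples, and the latent period is the last sampled time
#' before the titer first exceeds \code{baseline * rise_factor}.
#'
#' @param series A \code{\link{titer_series}} from a one-step growth assay.
#' @param rise_factor Detection threshold as a multiple of baseline
#'   (default 2).
#' @return Latent period in minutes.
#' @export
estimate_latent_period <- function(series, rise_factor = 2.0) {
  if (!inherits(series, "titer_series")) pc_stop("`series` must be a titer_series")
  series <- replicate_mean(series)
  if (nrow(series) < 4L) pc_stop("latent-period estimation needs at least 4 time points")
  baseline <- mean(series$titer_pfu_ml[1:2])
  threshold <- baseline * rise_factor
  above <- which(series$titer_pfu_ml > threshold)
  if (!length(above)) {
    pc_stop("no sample exceeds the rise threshold: no burst detected",
            class = "phagechar_no_burst")
  }
  first <- above[1]
  if (first == 1L) {
    pc_stop("first sample already above the rise threshold: curve has no pre-burst baseline",
            class = "phagechar_degenerate_input")
  }
  series$time_min[first - 1L]
}

#' Estimate the burst size from a one-step growth curve
#'
#' The burst size is the final free-phage titer divided by the number of
#' infected cells. The final titer is the mean of the last
#' \code{plateau_n} samples, which should form a plateau (relative spread
#' below 20%); if they do not, a warning is issued and the last sample
#' alone is used.
#'
#' @param series A \code{\link{titer_series}} from a one-step growth assay.
#' @param infected_cells Infected cells per ml, > 0 (see
#'   \code{\link{infected_cell_count}}).
#' @param plateau_n Number of trailing samples averaged (default 3).
#' @return Burst size (progeny phage per infected cell).
#' @export
estimate_burst_size <- function(series, infected_cells, plateau_n = 3) {
  if (!inherits(series, "titer_series")) pc_stop("`series` must be a titer_series")
  if (!is.numeric(infected_cells) || length(infected_cells) != 1L ||
      is.na(infected_cells) || infected_cells <= 0) {
    pc_stop("`infected_cells` must be a single positive number")
  }
  series <- replicate_mean(series)
  n <- nrow(series)
  plateau_n <- min(plateau_n, n)
  tail_titers <- series$titer_pfu_ml[(n - plateau_n + 1L):n]
  spread <- (max(tail_titers) - min(tail_titers)) / mean(tail_titers)
  if (is.finite(spread) && spread >= 0.2) {
    pc_warn("trailing samples do not form a plateau (spread >= 20%); using the final sample")
    tail_titers <- series$titer_pfu_ml[n]
  }
  mean(tail_titers) / infected_cells
}

#' Infected cells from total phage and adsorbed fraction
#'
#' At low MOI (e.g. 0.001) essentially every adsorbed phage infects a
#' distinct cell, so infected cells = total phage x adsorbed fraction.
#' With \code{poisson_correction = TRUE} and a cell concentration supplied,
#' multiple infection is corrected via cells x (1 - exp(-m)) where m is
#' the adsorbed-phage-per-cell ratio.
#'
#' @param p_total Total phage input (pfu/ml), >= 0.
#' @param adsorbed_fraction Fraction of phage adsorbed, in [0, 1].
#' @param poisson_correction Apply the multiple-infection correction.
#' @param cells Cell concentration (cfu/ml); required for the correction.
#' @return Infected cells per ml.
#' @export
infected_cell_count <- function(p_total, adsorbed_fraction,
                                poisson_correction = FALSE, cells = NULL) {
  if (!is.numeric(adsorbed_fraction) || any(is.na(adsorbed_fraction)) ||
      any(adsorbed_fraction < 0) || any(adsorbed_fraction > 1)) {
    pc_stop("`adsorbed_fraction` must lie in [0, 1]")
  }
  if (any(p_total < 0)) pc_stop("`p_total` must be non-negative")
  adsorbed <- p_total * adsorbed_fraction
  if (!poisson_correction) return(adsorbed)
  if (is.null(cells) || any(cells <= 0)) {
    pc_stop("`cells` (> 0) is required for the Poisson multiple-infection correction")
  }
  cells * (1 - exp(-adsorbed / cells))
}

#' One-step growth analysis
#'
#' Convenience wrapper combining \code{\link{estimate_latent_period}} and
#' \code{\link{estimate_burst_size}}.
#'
#' @inheritParams estimate_latent_period
#' @inheritParams estimate_burst_size
#' @return A list of class \code{"onestep_result"} with
#'   \code{latent_period} (min), \code{burst_size}, \code{baseline_titer},
#'   \code{plateau_titer} and \code{infected_cells}.
#' @export
onestep_analysis <- function(series, infected_cells, rise_factor = 2.0,
                             plateau_n = 3) {
  series_m <- replicate_mean(series)
  latent <- estimate_latent_period(series_m, rise_factor = rise_factor)
  burst <- estimate_burst_size(series_m, infected_cells, plateau_n = plateau_n)
  n <- nrow(series_m)
  structure(list(
    latent_period = latent,
    burst_size = burst,
    baseline_titer = mean(series_m$titer_pfu_ml[1:2]),
    plateau_titer = mean(series_m$titer_pfu_ml[(n - min(plateau_n, n) + 1L):n]),
    infected_cells = infected_cells
  ), class = "onestep_result")
}

#' @export
print.onestep_result <- function(x, ...) {
  cat("<onestep_result>\n")
  cat(sprintf("  latent period : %g min\n", x$latent_period))
  cat(sprintf("  burst size    : %.1f phage / infected cell\n", x$burst_size))
  cat(sprintf("  baseline      : %s pfu/ml\n", format_sci(x$baseline_titer)))
  cat(sprintf("  plateau       : %s pfu/ml\n", format_sci(x$plateau_titer)))
  invisible(x)
}
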