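#' @keywords internal
#' @importFrom stats aggregate as.dist coef rnorm rpois runif sd setNames
#' @importFrom utils head read.csv read.table write.csv
"_PACKAGE"

# Classed error helper so callers can distinguish bad inputs from bugs.
pc_stop <- function(msg, class = "phagechar_invalid_input", call. = FALSE) {
  stop(structure(
    class = c(class, "phagechar_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

pc_warn <- function(msg, class = "phagechar_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic generators funnel through this so identical (params, seed)
# pairs give identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    pc_stop("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round-half-up to `digits` decimals. base::round() rounds half to even,
# which disagrees with how assay percentages are conventionally reported
# (e.g. 60.75 -> 60.8, not 60.7 or 60.8 depending on parity).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a number in scientific notation at a fixed number of
#' significant digits
#'
#' Rate constants and mutant frequencies are conventionally reported as,
#' e.g., \code{"1.3e-09"}: two significant digits, scientific notation.
#'
#' @param x Numeric vector.
#' @param digits Significant digits (default 2).
#' @return Character vector.
#' @examples
#' format_sci(1.26e-9)  # "1.3e-09"
#' @export
format_sci <- function(x, digits = 2) {
  formatC(signif(x, digits), format = "e", digits = digits - 1)
}
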