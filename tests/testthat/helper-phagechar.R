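# Shared fixtures built in code.

# Sequence with an exact base composition (shuffled deterministically):
# `gc` G/C bases and `at` A/T bases, split as evenly as possible.
exact_composition_sequence <- function(gc, at, seed = 1L) {
  bases <- c(rep(c("G", "C"), c(ceiling(gc / 2), floor(gc / 2))),
             rep(c("A", "T"), c(ceiling(at / 2), floor(at / 2))))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  paste(withr_seed(sample(bases)), collapse = "")
}

# Step one-step-growth curve: flat baseline to `latent`, then a linear rise
# to plateau, sampled on a fixed grid. Noise-free.
step_curve <- function(latent, baseline = 1e5, amplitude = 1e7, rise = 15,
                       times = seq(0, 90, by = 3)) {
  titer <- ifelse(times < latent, baseline,
                  ifelse(times < latent + rise,
                         baseline + amplitude * (times - latent) / rise,
                         baseline + amplitude))
  titer_series(times, titer)
}

# Independent one-decimal round-half-up (mirrors assay reporting style).
round_half_up_test <- function(x) floor(x * 10 + 0.5) / 10

# Path to the synthetic host-range fixture shipped with the package.
host_range_fixture <- function() {
  system.file("extdata", "synthetic_host_range.csv", package = "phagechar",
              mustWork = TRUE)
}
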